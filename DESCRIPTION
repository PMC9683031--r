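Package: bccner
Title: Rule-Based Information Extraction from Basal Cell Carcinoma
    Histopathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cascaded, rule-based named-entity recognition system for basal
    cell carcinoma (BCC) histopathology reports: gazetteer (lexicon) lookup,
    declarative pattern-rule phases over annotation sequences, ConText-style
    negation and affirmation detection, section-aware record assembly and CSV
    output.  Ships the evaluation machinery used to validate such systems
    (strict/average/lenient partial-match precision, recall and F1,
    per-document macro averaging with confidence intervals, token-level
    Cohen's kappa, positive specific agreement and pairwise F1 for
    inter-annotator agreement), a hypergeometric token capture-probability
    estimator for sizing a gold-standard validation corpus, and a seeded
    synthetic report generator with exact gold-standard standoff annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
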