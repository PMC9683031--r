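test_that("general tokenization splits words, numbers and punctuation", {
  toks <- tokenize("no residual disease.")
  expect_equal(covered_text(toks, "no residual disease."),
               c("no", "residual", "disease", "."))
  expect_equal(toks$start, c(0L, 3L, 12L, 19L))
  expect_equal(toks$end, c(2L, 11L, 19L, 20L))
  expect_equal(ann_feature(toks, "kind"), c("word", "word", "word", "punct"))

  slashed <- tokenize("skin/lesion")
  expect_equal(covered_text(slashed, "skin/lesion"), c("skin", "/", "lesion"))

  dec <- tokenize("1.2 mm")
  expect_equal(covered_text(dec, "1.2 mm"), c("1.2", "mm"))
  expect_equal(ann_feature(dec, "kind"), c("number", "word"))
})

test_that("capture policy keeps only letter-initial alphanumeric runs", {
  expect_equal(covered_text(tokenize("1.2 mm", policy = "capture"), "1.2 mm"), "mm")
  expect_equal(
    covered_text(tokenize("BCC (nodular) 3mm T2", policy = "capture"),
                 "BCC (nodular) 3mm T2"),
    c("BCC", "nodular", "T2")
  )
  expect_equal(nrow(tokenize("", policy = "capture")), 0)
})

test_that("tokenization is deterministic and reconstructs the input", {
  texts <- c(
    "Peripheral clearance 1.5 mm at 3 o'clock.",
    "A. Skin ellipse 15 x 8 x 4 mm.",
    "Clinical details:\nLesion on the left cheek."
  )
  for (tx in texts) {
    t1 <- tokenize(tx)
    t2 <- tokenize(tx)
    expect_identical(t1, t2)
    # non-overlapping, and covered text matches the original at each offset
    expect_true(all(t1$start[-1] >= t1$end[-nrow(t1)]))
    expect_identical(covered_text(t1, tx),
                     substring(tx, t1$start + 1L, t1$end))
    # everything outside tokens is whitespace
    mask <- rep(TRUE, nchar(tx))
    for (i in seq_len(nrow(t1))) mask[(t1$start[i] + 1L):t1$end[i]] <- FALSE
    leftover <- strsplit(tx, "")[[1]][mask]
    expect_true(all(grepl("[[:space:]]", leftover)))
  }
})

test_that("sentence splitting honours terminators, newlines and guards", {
  expect_equal(nrow(split_sentences("Nodular BCC. Completely excised.")), 2)
  # decimal point is not a boundary
  s <- split_sentences("Diameter 1.2 mm. Clear.")
  expect_equal(nrow(s), 2)
  expect_equal(covered_text(s, "Diameter 1.2 mm. Clear.")[1], "Diameter 1.2 mm.")
  expect_error(split_sentences(""), "empty")
  expect_equal(nrow(split_sentences("single line without terminator")), 1)
  # abbreviation guard: "e.g." followed by lowercase does not split
  expect_equal(nrow(split_sentences("Margins involved, e.g. deep aspect.")), 1)
  # newline runs split even without a terminator
  expect_equal(nrow(split_sentences("Line one\nLine two")), 2)
})

test_that("every token lies in exactly one sentence on generated reports", {
  g <- generate_corpus(synth_config(n_reports = 4, seed = 3))
  for (i in seq_len(nrow(g$corpus))) {
    tx <- g$corpus$text[i]
    toks <- tokenize(tx)
    sents <- split_sentences(tx)
    for (t in seq_len(nrow(toks))) {
      holders <- sum(sents$start <= toks$start[t] & toks$end[t] <= sents$end)
      expect_equal(holders, 1)
    }
  }
})

test_that("section segmentation recovers headers and labels preamble", {
  txt <- "CLINICAL DETAILS:\nLesion noted.\nMACROSCOPY:\nEllipse of skin."
  secs <- segment_sections(txt)
  expect_equal(vapply(secs$features, `[[`, character(1), "label"),
               c("ClinicalDetails", "MacroscopicDetails"))
  # headerless free prose: one ReportDetails section spanning all text
  free <- segment_sections("A fragment of skin with tumour present.")
  expect_equal(nrow(free), 1)
  expect_equal(free$features[[1]]$label, "ReportDetails")
  expect_equal(free$end, nchar("A fragment of skin with tumour present."))
})

test_that("a synthetic proforma report yields all nine sections", {
  g <- generate_corpus(synth_config(n_reports = 12, seed = 5, template_fraction = 1))
  # force supplementary presence by scanning for a report that has one
  labels_of <- function(tx) {
    vapply(segment_sections(tx)$features, `[[`, character(1), "label")
  }
  found_all9 <- FALSE
  for (tx in g$corpus$text) {
    labs <- labels_of(tx)
    if (setequal(setdiff(labs, "ReportDetails"), setdiff(section_labels(), "ReportDetails")) &&
        "SupplementaryReport" %in% labs) {
      found_all9 <- TRUE
      expect_true(all(setdiff(section_labels(), labs) == character(0)))
    } else {
      expect_true(all(labs %in% section_labels()))
    }
  }
  expect_true(found_all9)
})
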