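# Seeded generator of BCC histopathology reports with exact gold-standard
# standoff annotations and structured records.  Report templates are composed
# from the same lexicons the shipped cascade matches on, so a noise-free
# generated corpus is fully recoverable by the pipeline; the generator's
# ground truth records character spans as the text is composed.

.synth_names <- c(
  "Harris", "Jones", "Patel", "Evans", "Thomas", "Williams", "Davies",
  "Roberts", "Lewis", "Morgan", "Hughes", "Price", "Owen", "Rees",
  "Jenkins", "Griffiths", "Edwards", "Phillips", "James", "Lloyd"
)
.synth_sites <- c("cheek", "nose", "ear", "forehead", "scalp", "neck",
                  "temple", "chin", "shoulder", "back")
.synth_subtypes <- c("nodular", "superficial", "infiltrative",
                     "micronodular", "morphoeic", "basosquamous")
.synth_levels <- c("dermis", "subcutis", "subcutaneous fat")
.synth_months <- c("January", "February", "March", "April", "May", "June",
                   "July", "August", "September", "October", "November",
                   "December")

#' Synthetic-corpus generation settings
#'
#' Defaults emulate the corpus shape the system targets: about 1.5 BCC
#' lesions per report, roughly 7% of reports written on a structured
#' proforma, and a bank of 20 simulated report-writer styles.
#'
#' @param n_reports Number of reports to generate.
#' @param lesion_distribution Named probabilities over lesions per report
#'   (names are lesion counts); the default has mean 1.5.
#' @param template_fraction Proportion of reports using the structured
#'   proforma layout.
#' @param negation_rate Probability that a mentioned prognostic factor is
#'   negated rather than asserted present.
#' @param style_bank Number of simulated report-writer styles (header
#'   synonyms, date formats, sentence variants).
#' @param noise Optional list of text perturbations; `list(spacing = p)`
#'   doubles the space after a sentence with probability `p`.
#' @param seed Integer seed; corpora are byte-identical for a fixed seed.
#' @return A `bcc_synth_config` list.
#' @export
synth_config <- function(n_reports = 200,
                         lesion_distribution = c("1" = 0.55, "2" = 0.40, "3" = 0.05),
                         template_fraction = 0.07,
                         negation_rate = 0.8,
                         style_bank = 20,
                         noise = NULL,
                         seed = 1) {
  if (n_reports < 1) abort("n_reports must be at least 1")
  if (abs(sum(lesion_distribution) - 1) > 1e-9) {
    abort("lesion_distribution probabilities must sum to 1")
  }
  if (any(lesion_distribution < 0) || template_fraction < 0 ||
      template_fraction > 1 || negation_rate < 0 || negation_rate > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      lesion_distribution = lesion_distribution,
      template_fraction = template_fraction,
      negation_rate = negation_rate,
      style_bank = as.integer(style_bank),
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "bcc_synth_config"
  )
}

fmt_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

# A text builder that records absolute spans as pieces are emitted.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- character()
  env$len <- 0L
  env$gold <- list()
  env
}
emit <- function(b, s) {
  start <- b$len
  b$pieces <- c(b$pieces, s)
  b$len <- b$len + nchar(s)
  invisible(start)
}
# emit `s`, registering a gold annotation over the part [from, to) of `s`
# (relative offsets; defaults to the whole piece)
emit_gold <- function(b, s, category, features, from = 0L, to = nchar(s)) {
  start <- emit(b, s)
  b$gold[[length(b$gold) + 1L]] <- list(
    category = category, start = start + from, end = start + to,
    features = features
  )
  invisible(start)
}
sentence_sep <- function(b, noise_spacing = 0) {
  if (noise_spacing > 0 && runif(1) < noise_spacing) emit(b, "  ") else emit(b, " ")
}

capitalize <- function(s) {
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

style_attrs <- function(style, headers) {
  pick <- function(label) {
    syns <- headers[[label]]
    syns[(style - 1L) %% length(syns) + 1L]
  }
  list(
    date_numeric = style %% 2L == 0L,
    clinical_variant = style %% 3L,
    macro_variant = style %% 2L,
    diag_variant = style %% 2L,
    header = vapply(section_labels(), pick, character(1))
  )
}

date_string <- function(day, month, year, numeric) {
  if (numeric) {
    sprintf("%02d/%02d/%d", day, month, year)
  } else {
    paste(day, .synth_months[month], year)
  }
}
date_iso <- function(day, month, year) sprintf("%d-%02d-%02d", year, month, day)

# Emit one measurement phrase and its gold annotation; returns nothing, all
# bookkeeping happens on the builder / record environment.
emit_measurement <- function(b, axis_label, axis, value, clock = NA_integer_,
                             colon = FALSE) {
  num <- fmt_num(value)
  body <- paste0(axis_label, if (colon) ": " else " ", num, " mm")
  if (!is.na(clock)) body <- paste0(body, " at ", clock, " o'clock")
  feats <- list(axis = axis, text = body, value_mm = value)
  if (!is.na(clock)) feats$clock <- as.integer(clock)
  emit_gold(b, body, "MicroscopicMeasurements", feats)
  emit(b, ".")
}

generate_document <- function(doc_id, style, is_template, cfg, headers) {
  b <- new_builder()
  ns <- if (is.null(cfg$noise)) 0 else (cfg$noise$spacing %||% 0)
  at <- style_attrs(style, headers)
  hdr <- function(label) paste0(capitalize(at$header[[label]]), ":")

  year <- sample(2016:2018, 1)
  exc <- c(sample(1:28, 1), sample(1:12, 1))
  rep_day <- c(sample(1:28, 1), exc[2])
  accession <- sprintf("SB%02d/%05d", year %% 100, sample(1:99999, 1))
  requestor <- paste("Dr", sample(.synth_names, 1))
  lat <- if (runif(1) < 0.8) sample(c("left", "right"), 1) else NULL
  site <- sample(.synth_sites, 1)
  site_phrase <- paste(c(lat, site), collapse = " ")
  n_lesions <- as.integer(sample(
    names(cfg$lesion_distribution), 1,
    prob = cfg$lesion_distribution
  ))
  labels <- if (is_template || n_lesions > 1) LETTERS[seq_len(n_lesions)] else "1"
  has_supp <- runif(1) < 0.05

  lesions <- lapply(seq_len(n_lesions), function(i) {
    list(
      label = labels[i],
      subtype = sample(.synth_subtypes, 1),
      dims = c(sample(5:30, 1), sample(3:20, 1), sample(2:10, 1)),
      thickness = sample(5:80, 1) / 10,
      diameter = sample(2:30, 1),
      peripheral = sample(1:100, 1) / 10,
      clock = if (runif(1) < 0.6) sample(1:12, 1) else NA_integer_,
      deep = sample(1:80, 1) / 10,
      perineural_neg = runif(1) < cfg$negation_rate,
      lympho = runif(1) < 0.7,
      lympho_neg = runif(1) < cfg$negation_rate,
      ulcer = runif(1) < 0.4,
      ulcer_neg = runif(1) < cfg$negation_rate,
      residual = runif(1) < 0.3,
      level = if (runif(1) < 0.7) sample(.synth_levels, 1) else NULL,
      level_affirmed = runif(1) < 0.8,
      complete = runif(1) < 0.85
    )
  })

  marker <- function(les) if (les$label == "1") "" else paste0(les$label, ". ")

  if (is_template) emit(b, "BCC EXCISION PROFORMA\n")

  # accession / excision date
  emit(b, paste0(hdr("AccessionNumber"), " "))
  emit_gold(b, accession, "AccessionNumber", list(value = accession))
  emit(b, "\n")
  ds <- date_string(exc[1], exc[2], year, at$date_numeric)
  emit(b, paste0(hdr("ExcisionDate"), " "))
  emit_gold(b, ds, "ExcisionDate",
            list(value = ds, date_iso = date_iso(exc[1], exc[2], year)))
  emit(b, "\n")

  # clinical details
  emit(b, paste0(hdr("ClinicalDetails"), if (is_template) " " else "\n"))
  site_gold <- function() {
    emit_gold(b, site_phrase, "ClinicalDetails", list(site = tolower(site_phrase)))
  }
  if (at$clinical_variant == 0L) {
    emit(b, "Lesion on the ")
    site_gold()
    emit(b, ".")
  } else if (at$clinical_variant == 1L) {
    emit(b, "Excision of lesion from the ")
    site_gold()
    emit(b, ".")
  } else {
    emit(b, "Skin lesion, ")
    site_gold()
    emit(b, ".")
  }
  emit(b, "\n")

  # macroscopic details
  emit(b, paste0(hdr("MacroscopicDetails"), "\n"))
  for (les in lesions) {
    dims_txt <- paste0(les$dims[1], " x ", les$dims[2], " x ", les$dims[3], " mm")
    emit(b, marker(les))
    if (at$macro_variant == 0L) emit(b, "Ellipse of skin measuring ")
    else emit(b, "Skin ellipse ")
    emit_gold(b, dims_txt, "MacroscopicDetails", list(
      specimen_dimensions = dims_txt,
      dim1_mm = les$dims[1], dim2_mm = les$dims[2], dim3_mm = les$dims[3]
    ))
    emit(b, ".\n")
  }

  # microscopic details
  emit(b, paste0(hdr("MicroscopicDetails"), "\n"))
  for (les in lesions) {
    emit(b, marker(les))
    diag_txt <- paste(les$subtype, "basal cell carcinoma")
    if (at$diag_variant == 0L) {
      emit_gold(b, capitalize(diag_txt), "MicroscopicDetails",
                list(subtype = les$subtype, tag = "bcc"))
    } else {
      emit(b, "Sections show ")
      emit_gold(b, diag_txt, "MicroscopicDetails",
                list(subtype = les$subtype, tag = "bcc"))
    }
    emit(b, ".")
    factor_gold <- function(term, negated) {
      feats <- list(factor = term)
      if (negated) feats$negated <- TRUE
      feats
    }
    sentence_sep(b, ns)
    if (les$perineural_neg) {
      emit(b, "There is no ")
      emit_gold(b, "perineural invasion", "MicroscopicDetails",
                factor_gold("perineural invasion", TRUE))
      emit(b, ".")
    } else {
      emit_gold(b, "Perineural invasion", "MicroscopicDetails",
                factor_gold("perineural invasion", FALSE))
      emit(b, " is present.")
    }
    if (les$lympho) {
      sentence_sep(b, ns)
      if (les$lympho_neg) {
        emit(b, "No ")
        emit_gold(b, "lymphovascular invasion", "MicroscopicDetails",
                  factor_gold("lymphovascular invasion", TRUE))
        emit(b, " is seen.")
      } else {
        emit_gold(b, "Lymphovascular invasion", "MicroscopicDetails",
                  factor_gold("lymphovascular invasion", FALSE))
        emit(b, " is present.")
      }
    }
    if (les$ulcer) {
      sentence_sep(b, ns)
      if (les$ulcer_neg) {
        emit(b, "There is no ")
        emit_gold(b, "ulceration", "MicroscopicDetails",
                  factor_gold("ulceration", TRUE))
        emit(b, ".")
      } else {
        emit_gold(b, "Ulceration", "MicroscopicDetails",
                  factor_gold("ulceration", FALSE))
        emit(b, " is present.")
      }
    }
    if (les$residual) {
      sentence_sep(b, ns)
      emit(b, "There was no ")
      emit_gold(b, "residual disease", "MicroscopicDetails",
                factor_gold("residual disease", TRUE))
      emit(b, ".")
    }
    if (!is.null(les$level)) {
      sentence_sep(b, ns)
      lf <- list(level = les$level)
      if (les$level_affirmed) {
        lf$affirmed <- TRUE
        emit(b, "Tumour confined to the ")
        emit_gold(b, les$level, "MicroscopicDetails", lf)
        emit(b, ".")
      } else {
        emit(b, "The tumour reaches the ")
        emit_gold(b, les$level, "MicroscopicDetails", lf)
        emit(b, ".")
      }
    }
    sentence_sep(b, ns)
    emit(b, "The lesion is ")
    if (les$complete) {
      emit_gold(b, "completely excised", "MicroscopicDetails",
                list(excision = "complete"))
    } else {
      emit_gold(b, "incompletely excised", "MicroscopicDetails",
                list(excision = "incomplete"))
    }
    emit(b, ".\n")
  }

  # microscopic measurements
  emit(b, paste0(hdr("MicroscopicMeasurements"), "\n"))
  for (les in lesions) {
    emit(b, marker(les))
    emit_measurement(b, "Tumour thickness", "thickness", les$thickness,
                     colon = is_template)
    sentence_sep(b, ns)
    emit_measurement(b, "Tumour diameter", "diameter", les$diameter,
                     colon = is_template)
    sentence_sep(b, ns)
    emit_measurement(b, "Peripheral clearance", "peripheral", les$peripheral,
                     clock = les$clock, colon = is_template)
    sentence_sep(b, ns)
    emit_measurement(b, "Deep clearance", "deep", les$deep,
                     colon = is_template)
    emit(b, "\n")
  }

  # report details / requestor / supplementary
  emit(b, paste0(hdr("ReportDetails"), " Report authorised "))
  rs <- date_string(rep_day[1], rep_day[2], year, at$date_numeric)
  emit_gold(b, rs, "ReportDetails",
            list(value = rs, date_iso = date_iso(rep_day[1], rep_day[2], year)))
  emit(b, ".\n")
  emit(b, paste0(hdr("Requestor"), " "))
  emit_gold(b, requestor, "Requestor", list(name = tolower(requestor)))
  emit(b, "\n")
  if (has_supp) {
    emit(b, paste0(hdr("SupplementaryReport"), " Immunohistochemistry confirms "))
    emit_gold(b, "basal cell carcinoma", "SupplementaryReport",
              list(supplementary_tag = "bcc"))
    emit(b, ".\n")
  }

  text <- paste(b$pieces, collapse = "")
  gold <- annotation_tbl(
    category = map_chr(b$gold, "category"),
    start = map_int(b$gold, function(g) as.integer(g$start)),
    end = map_int(b$gold, function(g) as.integer(g$end)),
    features = map(b$gold, "features")
  )

  # structured ground-truth records, one per lesion, mirroring the record
  # columns the pipeline assembles
  recs <- lapply(lesions, function(les) {
    list(
      report_id = doc_id, specimen = les$label, lesion = 1L,
      accession_number = accession,
      excision_date = date_iso(exc[1], exc[2], year),
      site = tolower(site_phrase),
      specimen_dim1_mm = as.character(les$dims[1]),
      specimen_dim2_mm = as.character(les$dims[2]),
      specimen_dim3_mm = as.character(les$dims[3]),
      tag = "bcc", subtype = les$subtype,
      perineural_invasion = if (les$perineural_neg) "negated" else "present",
      lymphovascular_invasion = if (les$lympho) {
        if (les$lympho_neg) "negated" else "present"
      } else NA_character_,
      ulceration = if (les$ulcer) {
        if (les$ulcer_neg) "negated" else "present"
      } else NA_character_,
      residual_disease = if (les$residual) "negated" else NA_character_,
      level_of_invasion = if (!is.null(les$level)) les$level else NA_character_,
      completeness_of_excision = if (les$complete) "complete" else "incomplete",
      tumour_thickness_mm = as.character(les$thickness),
      tumour_diameter_mm = as.character(les$diameter),
      peripheral_clearance_mm = as.character(les$peripheral),
      peripheral_clearance_clock = if (is.na(les$clock)) NA_character_ else as.character(les$clock),
      deep_clearance_mm = as.character(les$deep),
      report_date = date_iso(rep_day[1], rep_day[2], year),
      requestor = tolower(requestor),
      supplementary_tag = if (has_supp) "bcc" else NA_character_
    )
  })
  list(text = text, gold = gold, records = recs, n_lesions = n_lesions)
}

#' Generate a synthetic BCC report corpus with gold annotations
#'
#' Deterministic for a fixed seed (each document draws from its own derived
#' random stream, so corpora are reproducible under any generation order).
#' Returns the corpus, corpus-level gold standoff annotations, ground-truth
#' records and a manifest summarising realized lesion counts and template
#' fraction.
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (doc_id, text), `gold` (annotation tibble with
#'   `doc_id`, `set = "gold"`), `records` (one row per lesion) and
#'   `manifest`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "bcc_synth_config"))
  headers <- default_section_headers()
  n <- config$n_reports
  set.seed(config$seed)
  is_template <- runif(n) < config$template_fraction
  styles <- sample.int(config$style_bank, n, replace = TRUE)
  doc_seeds <- (config$seed + 7919L * seq_len(n)) %% 2147483647L
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(doc_seeds[i])
    doc_id <- sprintf("report-%04d", i)
    docs[[i]] <- generate_document(doc_id, styles[i], is_template[i], config, headers)
    docs[[i]]$doc_id <- doc_id
  }
  corpus <- corpus_tbl(
    doc_id = map_chr(docs, "doc_id"),
    text = map_chr(docs, "text")
  )
  gold <- list_rbind(lapply(docs, function(d) {
    g <- d$gold
    g$doc_id <- d$doc_id
    g$set <- "gold"
    g
  }))
  rec_cols <- names(docs[[1]]$records[[1]])
  records <- list_rbind(lapply(docs, function(d) {
    list_rbind(lapply(d$records, function(r) as_tibble(r[rec_cols])))
  }))
  manifest <- list(
    n_reports = n,
    seed = config$seed,
    template_fraction = config$template_fraction,
    realized_template_fraction = mean(is_template),
    lesions_planted = sum(map_int(docs, "n_lesions")),
    mean_lesions_per_report = mean(map_int(docs, "n_lesions")),
    style_bank = config$style_bank,
    layout = "synthetic reconstruction of a nine-section BCC report; headers and phrasing are plausible, not copies of any health-board format"
  )
  list(corpus = corpus, gold = gold, records = records, manifest = manifest)
}

#' Derive two simulated annotators from a gold standard
#'
#' Each annotator is an independent perturbation of the gold set: with
#' probability `rate` per annotation the annotation is dropped, its span
#' jittered, or one feature value flipped (`perturbation = "mixed"`), or
#' always dropped (`perturbation = "drop"`).  Used to exercise the
#' inter-annotator-agreement machinery end to end.
#'
#' @param gold Corpus-level gold annotation tibble from [generate_corpus()].
#' @param corpus Matching corpus tibble (for text lengths when jittering).
#' @param rate Per-annotation disagreement probability in \[0, 1\].
#' @param seed Integer seed.
#' @param perturbation `"mixed"` or `"drop"`.
#' @return Annotation tibble with sets `"annotatorA"` and `"annotatorB"`.
#' @export
generate_annotator_pair <- function(gold, corpus, rate, seed = 1,
                                    perturbation = c("mixed", "drop")) {
  perturbation <- match.arg(perturbation)
  stopifnot(rate >= 0, rate <= 1)
  text_len <- setNames(nchar(corpus$text), corpus$doc_id)
  perturb_set <- function(label, sub_seed) {
    set.seed(sub_seed)
    g <- gold
    keep <- rep(TRUE, nrow(g))
    for (i in seq_len(nrow(g))) {
      if (runif(1) >= rate) next
      kind <- if (perturbation == "drop") "drop" else {
        sample(c("drop", "jitter", "flip"), 1, prob = c(0.5, 0.25, 0.25))
      }
      if (kind == "drop") {
        keep[i] <- FALSE
      } else if (kind == "jitter") {
        lim <- text_len[[g$doc_id[i]]]
        delta <- sample(c(-2L, -1L, 1L, 2L), 1)
        new_end <- min(lim, max(g$start[i] + 1L, g$end[i] + delta))
        g$end[i] <- new_end
      } else {
        f <- g$features[[i]]
        if (length(f) > 0) {
          nm <- names(f)[1]
          f[[nm]] <- paste0(as.character(f[[nm]]), "_x")
          g$features[[i]] <- f
        } else {
          keep[i] <- FALSE
        }
      }
    }
    g <- g[keep, , drop = FALSE]
    g$set <- label
    g
  }
  bind_rows(
    perturb_set("annotatorA", seed * 2L + 1L),
    perturb_set("annotatorB", seed * 2L + 2L)
  )
}
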