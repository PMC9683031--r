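# End-to-end BCC extraction: resource loading, the full annotation pipeline
# (tokens -> sentences -> sections -> lookup -> rule cascade -> ConText),
# section attribution and cleanup, measurement/date post-processing,
# per-specimen record assembly and CSV output.

#' Load and validate a resource bundle
#'
#' A resource directory holds a `config.yaml` naming the gazetteer index,
#' rule cascade directory, trigger lexicon and schema, plus tokenizer policy
#' and section-header synonyms.  All resources are validated at load time;
#' any failure aborts before a document is touched.
#'
#' @param dir Resource directory; defaults to the BCC bundle shipped with
#'   the package.
#' @return A `bcc_resources` object.
#' @export
bcc_resources <- function(dir = system.file("extdata", "bcc", package = "bccner")) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) abort(paste0("no config.yaml under ", dir))
  cfg <- yaml::read_yaml(cfg_path)
  policy <- cfg$tokenizer$policy %||% "general"
  headers <- cfg$sections$headers
  if (is.null(headers) || identical(headers, "default")) {
    headers <- default_section_headers()
  } else {
    bad <- setdiff(names(headers), section_labels())
    if (length(bad) > 0) {
      abort(paste0("unknown section labels in config: ", paste(bad, collapse = ", ")))
    }
    headers <- lapply(headers, function(x) as.character(unlist(x)))
  }
  entries <- read_gazetteer_index(file.path(dir, cfg$resources$gazetteers %||% "gazetteers/index.def"))
  index <- compile_gazetteer(entries)
  cascade <- read_cascade(file.path(dir, cfg$resources$rules %||% "rules"))
  triggers <- read_triggers(file.path(dir, cfg$resources$triggers %||% "triggers/context.lst"))
  schema <- read_schema(file.path(dir, cfg$resources$schema %||% "schema.yaml"))
  files <- c(
    cfg_path,
    file.path(dir, cfg$resources$schema %||% "schema.yaml"),
    file.path(dir, cfg$resources$triggers %||% "triggers/context.lst"),
    list.files(file.path(dir, cfg$resources$rules %||% "rules"), full.names = TRUE),
    list.files(file.path(dir, dirname(cfg$resources$gazetteers %||% "gazetteers/index.def")),
               full.names = TRUE)
  )
  structure(
    list(
      dir = dir, policy = policy, headers = headers, index = index,
      cascade = cascade, triggers = triggers, schema = schema,
      files = sort(unique(files)),
      window_tokens = cfg$context$window_tokens %||% Inf
    ),
    class = "bcc_resources"
  )
}

#' @export
print.bcc_resources <- function(x, ...) {
  cat("<bcc_resources> ", nrow(x$index$entries), " gazetteer entries, ",
      length(x$cascade), " rule phases, ",
      nrow(x$triggers), " context triggers\n", sep = "")
  invisible(x)
}

.entity_targets <- function() setdiff(section_labels(), character())

month_numbers <- setNames(1:12, c(
  "january", "february", "march", "april", "may", "june", "july",
  "august", "september", "october", "november", "december"
))

# "14/03/2016" or "14 March 2016" -> "2016-03-14"; NA when unparseable.
parse_report_date <- function(txt) {
  txt <- trimws(tolower(txt))
  m <- stringr::str_match(txt, "^(\\d{1,2})[/. -](\\d{1,2})[/. -](\\d{4})$")
  if (!is.na(m[1, 1])) {
    return(sprintf("%s-%02d-%02d", m[1, 4], as.integer(m[1, 3]), as.integer(m[1, 2])))
  }
  m <- stringr::str_match(txt, "^(\\d{1,2})\\s+([a-z]+)\\s+(\\d{4})$")
  if (!is.na(m[1, 1]) && m[1, 3] %in% names(month_numbers)) {
    return(sprintf("%s-%02d-%02d", m[1, 4], month_numbers[[m[1, 3]]], as.integer(m[1, 2])))
  }
  NA_character_
}

# Post-cascade enrichment: ISO dates on date entities, numeric measurement
# features, dimension triplets on macroscopic entities.
postprocess_entities <- function(anns, text) {
  for (i in seq_len(nrow(anns))) {
    cat <- anns$category[i]
    f <- anns$features[[i]]
    if (cat %in% c("ExcisionDate", "ReportDetails") && !is.null(f$value)) {
      iso <- parse_report_date(f$value)
      if (!is.na(iso)) anns$features[[i]]$date_iso <- iso
    } else if (cat == "MicroscopicMeasurements" && !is.null(f$text)) {
      meas <- parse_measurement(f$text, axis = f$axis)
      if (nrow(meas) == 1) {
        anns$features[[i]]$value_mm <- meas$value[1]
        if (!is.na(meas$clock[1])) anns$features[[i]]$clock <- meas$clock[1]
      }
    } else if (cat == "MacroscopicDetails" && !is.null(f$specimen_dimensions)) {
      meas <- parse_measurement(f$specimen_dimensions)
      if (nrow(meas) >= 1) {
        for (k in seq_len(nrow(meas))) {
          anns$features[[i]][[paste0("dim", k, "_mm")]] <- meas$value[k]
        }
      }
    }
  }
  anns
}

# Attach the enclosing section label to every entity annotation, then drop
# entities whose category disagrees with their section (the cascade's
# remove-from-output behaviour for out-of-place matches).
attribute_sections <- function(anns) {
  sections <- ann_select(anns, "Section")
  entity_rows <- which(anns$category %in% section_labels())
  drop <- integer()
  for (i in entity_rows) {
    enc <- sections[sections$start <= anns$start[i] & anns$end[i] <= sections$end, ]
    if (nrow(enc) == 0) {
      drop <- c(drop, i)
      next
    }
    label <- enc$features[[nrow(enc)]]$label # innermost (sections don't nest; last = latest start)
    if (!identical(label, anns$category[i])) {
      drop <- c(drop, i)
    } else {
      anns$features[[i]]$section <- label
    }
  }
  if (length(drop) > 0) anns <- anns[-drop, , drop = FALSE]
  anns
}

#' Annotate one report with the full pipeline
#'
#' Runs tokenisation, sentence splitting, section segmentation, gazetteer
#' lookup, the rule cascade, ConText polarity detection, section attribution
#' (entities whose category disagrees with their enclosing section are
#' removed from the output) and measurement/date post-processing.
#'
#' @param text Report text (non-empty).
#' @param res A `bcc_resources` bundle.
#' @return An annotation table holding auxiliary annotations (`Token`,
#'   `Sentence`, `Section`) and the extracted entity annotations.
#' @export
bcc_annotate <- function(text, res) {
  stopifnot(inherits(res, "bcc_resources"))
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    abort("cannot annotate an empty document")
  }
  tokens <- tokenize(text, policy = res$policy)
  sentences <- split_sentences(text)
  sections <- segment_sections(text, headers = res$headers)
  base <- bind_rows(tokens, sentences, sections)
  base$id <- seq_len(nrow(base))
  lookups <- gaz_lookup(text, tokens, res$index)
  if (nrow(lookups) > 0) lookups$id <- max(base$id) + seq_len(nrow(lookups))
  anns <- validate_annotations(bind_rows(base, lookups))
  anns <- run_cascade(res$cascade, text, anns)
  anns <- apply_context(text, anns, targets = section_labels(),
                        triggers = res$triggers,
                        window_tokens = res$window_tokens)
  anns <- attribute_sections(anns)
  anns <- postprocess_entities(anns, text)
  validate_annotations(anns, text_len = nchar(text))
}

#' Extract the entity annotations (the "system" set) from a pipeline run
#'
#' @param anns Output of [bcc_annotate()].
#' @return Annotation table restricted to the nine entity categories.
#' @export
system_annotations <- function(anns) {
  ann_select(anns, category = section_labels())
}

# ---- specimen segmentation and record assembly ------------------------------

# Line-initial specimen labels ("A.", "B)", "1.") within a section open a
# specimen context inherited by subsequent entities of the same section.
specimen_markers <- function(text) {
  m <- gregexpr("(?m)^[ \\t]*([A-Z0-9])[.)][ \\t]", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(start = integer(), label = character()))
  starts <- as.integer(m) - 1L
  lab_start <- as.integer(attr(m, "capture.start")[, 1]) - 1L
  tibble(start = starts, label = substring(text, lab_start + 1L, lab_start + 1L))
}

feature_or_na <- function(f, name) {
  v <- f[[name]]
  if (is.null(v)) NA else v
}

polarity_value <- function(f) {
  if (isTRUE(f$negated)) "negated"
  else if (isTRUE(f$affirmed)) "affirmed"
  else "present"
}

#' Assemble per-specimen, per-lesion records from entity annotations
#'
#' Report-level fields (accession number, dates, requestor, clinical site)
#' are replicated onto every lesion row; specimen-scoped fields come from
#' the entities between one specimen label and the next within the
#' macroscopic/microscopic sections.  Reports without specimen labels get a
#' single implicit specimen `"1"`.
#'
#' @param doc_id Report identifier.
#' @param text Report text.
#' @param anns Pipeline annotations from [bcc_annotate()].
#' @param schema A `bcc_schema`.
#' @return A tibble, one row per (report, specimen, lesion), columns
#'   `report_id`, `specimen`, `lesion` plus the schema features in
#'   declaration order.
#' @export
assemble_records <- function(doc_id, text, anns, schema) {
  ents <- system_annotations(anns)
  markers <- specimen_markers(text)
  specimen_of <- function(start) {
    prior <- markers$label[markers$start <= start]
    if (length(prior) == 0) "1" else prior[length(prior)]
  }
  report_fields <- list()
  grab_first <- function(category, fname, transform = identity) {
    rows <- which(ents$category == category)
    for (i in rows) {
      v <- ents$features[[i]][[fname]]
      if (!is.null(v)) return(transform(v))
    }
    NA
  }
  report_fields$accession_number <- grab_first("AccessionNumber", "value")
  report_fields$excision_date <- grab_first("ExcisionDate", "date_iso")
  report_fields$report_date <- grab_first("ReportDetails", "date_iso")
  report_fields$requestor <- grab_first("Requestor", "name")
  report_fields$site <- grab_first("ClinicalDetails", "site")
  report_fields$supplementary_tag <- grab_first("SupplementaryReport", "supplementary_tag")

  scoped <- c("MacroscopicDetails", "MicroscopicDetails", "MicroscopicMeasurements")
  spec_rows <- which(ents$category %in% scoped)
  specimens <- unique(vapply(
    spec_rows,
    function(i) specimen_of(ents$start[i]), character(1)
  ))
  if (length(specimens) == 0) specimens <- "1"
  specimens <- sort(specimens)

  rows <- lapply(specimens, function(sp) {
    rec <- c(list(report_id = doc_id, specimen = sp, lesion = 1L), report_fields)
    for (i in spec_rows) {
      if (!identical(specimen_of(ents$start[i]), sp)) next
      f <- ents$features[[i]]
      cat <- ents$category[i]
      if (cat == "MacroscopicDetails") {
        for (k in 1:3) {
          v <- f[[paste0("dim", k, "_mm")]]
          if (!is.null(v)) rec[[paste0("specimen_dim", k, "_mm")]] <- v
        }
      } else if (cat == "MicroscopicDetails") {
        if (!is.null(f$tag)) rec$tag <- f$tag
        if (!is.null(f$subtype)) rec$subtype <- f$subtype
        if (!is.null(f$factor)) {
          col <- gsub(" ", "_", f$factor)
          rec[[col]] <- polarity_value(f)
        }
        if (!is.null(f$level)) rec$level_of_invasion <- f$level
        if (!is.null(f$excision)) rec$completeness_of_excision <- f$excision
      } else if (cat == "MicroscopicMeasurements") {
        v <- f$value_mm
        if (is.null(v)) next
        ax <- f$axis %||% ""
        if (ax == "thickness") rec$tumour_thickness_mm <- v
        if (ax == "diameter") rec$tumour_diameter_mm <- v
        if (ax == "peripheral") {
          rec$peripheral_clearance_mm <- v
          if (!is.null(f$clock)) rec$peripheral_clearance_clock <- f$clock
        }
        if (ax == "deep") rec$deep_clearance_mm <- v
      }
    }
    rec
  })
  cols <- c("report_id", "specimen", "lesion", schema_features(schema))
  out <- lapply(rows, function(rec) {
    vals <- lapply(cols, function(cl) {
      v <- rec[[cl]]
      if (is.null(v) || (length(v) == 1 && is.na(v))) NA_character_ else as.character(v)
    })
    setNames(vals, cols)
  })
  out <- as_tibble(do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE))))
  out$lesion <- as.integer(out$lesion)
  out
}

#' Run the full extraction over a corpus
#'
#' @param corpus Corpus tibble (`doc_id`, `text`), see [corpus_tbl()] /
#'   [read_corpus()].
#' @param res A `bcc_resources` bundle.
#' @return A list with `annotations` (corpus-level annotation tibble with
#'   `doc_id` and `set = "system"`, entity categories only) and `records`
#'   (one row per report/specimen/lesion).
#' @export
bcc_extract <- function(corpus, res) {
  stopifnot(inherits(res, "bcc_resources"), is.data.frame(corpus))
  ann_list <- list()
  rec_list <- list()
  for (i in seq_len(nrow(corpus))) {
    anns <- bcc_annotate(corpus$text[i], res)
    ents <- system_annotations(anns)
    if (nrow(ents) > 0) {
      ents$doc_id <- corpus$doc_id[i]
      ents$set <- "system"
      ann_list[[length(ann_list) + 1L]] <- ents
    }
    rec_list[[i]] <- assemble_records(corpus$doc_id[i], corpus$text[i], anns, res$schema)
  }
  list(
    annotations = if (length(ann_list) > 0) bind_rows(ann_list) else tibble(),
    records = bind_rows(rec_list)
  )
}

#' Write specimen records to CSV
#'
#' RFC-4180 CSV, one row per (report, specimen, lesion), stable column order
#' (id triplet, then schema declaration order).  Absent values are empty
#' fields.  The file is written to a temporary path and atomically renamed,
#' so no partial file is left behind.  A provenance sidecar
#' (`<file>.provenance.json`, resource file checksums) is written alongside
#' when `res` is supplied.
#'
#' @param records Record tibble from [bcc_extract()] / [assemble_records()].
#' @param path Destination CSV path.
#' @param res Optional `bcc_resources` for the provenance sidecar.
#' @return Number of data rows written, invisibly.
#' @export
write_records_csv <- function(records, path, res = NULL) {
  tmp <- paste0(path, ".tmp-", Sys.getpid())
  readr::write_csv(records, tmp, na = "")
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    abort(paste0("cannot write ", path))
  }
  if (!is.null(res)) {
    sums <- tools::md5sum(res$files)
    jsonlite::write_json(
      list(resources = as.list(sums)),
      paste0(path, ".provenance.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(nrow(records))
}
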