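# Annotation data model: typed character spans with flat feature maps, held in
# tibbles so they compose with dplyr.  Offsets are 0-based, half-open
# [start, end) into the unmodified report text.

#' Do two spans overlap?
#'
#' Spans are 0-based, half-open character intervals `[start, end)`.  Two spans
#' overlap when they share at least one character; adjacency (`end == start`)
#' is not overlap.  Vectorised over all four arguments.
#'
#' @param start1,end1 Integer offsets of the first span.
#' @param start2,end2 Integer offsets of the second span.
#'
#' @return A logical vector.
#' @examples
#' span_overlaps(0, 5, 3, 8)  # TRUE, shares characters 3-4
#' span_overlaps(0, 5, 5, 9)  # FALSE, half-open adjacency
#' @export
span_overlaps <- function(start1, end1, start2, end2) {
  check_spans(start1, end1)
  check_spans(start2, end2)
  start1 < end2 & start2 < end1
}

#' Are two spans coextensive?
#'
#' Coextensive spans have identical start and end offsets.  Coextensive
#' implies overlapping (spans are non-empty).
#'
#' @inheritParams span_overlaps
#' @return A logical vector.
#' @export
span_coextensive <- function(start1, end1, start2, end2) {
  check_spans(start1, end1)
  check_spans(start2, end2)
  start1 == start2 & end1 == end2
}

check_spans <- function(start, end) {
  if (any(is.na(start)) || any(is.na(end))) {
    abort("span offsets must not be NA")
  }
  if (any(start < 0)) {
    abort("span start offsets must be >= 0")
  }
  if (any(end <= start)) {
    abort("spans must be non-empty: start < end")
  }
  invisible(TRUE)
}

#' Build an annotation table
#'
#' The universal currency of the pipeline: a tibble with one row per
#' annotation and columns `id`, `category`, `start`, `end` and `features`
#' (a list column of named lists of scalars).  Rows are kept in span order:
#' `start` ascending, then `end` descending, so that longer annotations sort
#' before shorter ones starting at the same offset.
#'
#' @param category Character vector of entity-category names (e.g.
#'   `"MicroscopicDetails"`, or the auxiliary types `"Token"`, `"Sentence"`,
#'   `"Lookup"`, `"Section"`).
#' @param start,end Integer character offsets, 0-based half-open.
#' @param features List of named lists (one per annotation) of scalar feature
#'   values.  Missing entries are treated as empty feature maps.
#' @param id Optional integer ids, unique within the table; generated when
#'   omitted.
#'
#' @return A tibble of class `bcc_annotations`.
#' @examples
#' annotation_tbl(
#'   category = c("Token", "Token"),
#'   start = c(0L, 3L), end = c(2L, 7L),
#'   features = list(list(kind = "word"), list(kind = "word"))
#' )
#' @export
annotation_tbl <- function(category = character(), start = integer(),
                           end = integer(), features = NULL, id = NULL) {
  n <- length(category)
  stopifnot(length(start) == n, length(end) == n)
  if (is.null(features)) features <- rep(list(list()), n)
  stopifnot(length(features) == n)
  if (is.null(id)) id <- seq_len(n)
  out <- tibble(
    id = as.integer(id),
    category = as.character(category),
    start = as.integer(start),
    end = as.integer(end),
    features = lapply(features, as.list)
  )
  validate_annotations(out)
}

validate_annotations <- function(x, text_len = NULL) {
  stopifnot(is.data.frame(x))
  needed <- c("id", "category", "start", "end", "features")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "annotation table lacks column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) > 0) {
    check_spans(x$start, x$end)
    if (any(!nzchar(x$category))) abort("annotation categories must be non-empty")
    if (anyDuplicated(x$id)) abort("annotation ids must be unique within a set")
    if (!is.null(text_len) && any(x$end > text_len)) {
      abort("annotation spans must lie within the document text")
    }
    bad <- vapply(
      x$features,
      function(f) length(f) > 0 && (is.null(names(f)) || anyDuplicated(names(f)) > 0),
      logical(1)
    )
    if (any(bad)) abort("feature names must be present and unique within an annotation")
  }
  x <- x[order(x$start, -x$end, x$id), , drop = FALSE]
  class(x) <- unique(c("bcc_annotations", class(as_tibble(x))))
  as_tibble(x)
}

#' Select annotations by category and window
#'
#' Returns all annotations of `category` whose span overlaps the window
#' `[start, end)`, in span order (start ascending, then end descending so the
#' longest annotation at a shared start comes first).  Repeated calls on an
#' unmodified table return identical results.
#'
#' @param anns An annotation table (see [annotation_tbl()]).
#' @param category Category name to select, or `NULL` for all categories.
#' @param start,end Window offsets; defaults select everything.
#'
#' @return The matching rows, ordered.
#' @export
ann_select <- function(anns, category = NULL, start = 0L, end = Inf) {
  stopifnot(is.data.frame(anns))
  out <- anns
  if (!is.null(category)) out <- out[out$category %in% category, , drop = FALSE]
  if (nrow(out) > 0 && (start > 0 || is.finite(end))) {
    keep <- out$start < end & start < out$end
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$start, -out$end, out$id), , drop = FALSE]
}

#' Fetch one feature value from an annotation table
#'
#' @param anns Annotation table.
#' @param name Feature name.
#' @param default Value used where the feature is absent.
#' @return A vector (simplified when all values are scalars of one type).
#' @export
ann_feature <- function(anns, name, default = NA) {
  vals <- lapply(anns$features, function(f) f[[name]] %||% default)
  if (all(vapply(vals, function(v) is.atomic(v) && length(v) == 1, logical(1)))) {
    return(unlist(vals, use.names = FALSE))
  }
  vals
}

#' Extract the text covered by annotations
#'
#' @param anns Annotation table.
#' @param text The document text the offsets index into.
#' @return Character vector of covered substrings.
#' @export
covered_text <- function(anns, text) {
  if (nrow(anns) == 0) return(character())
  substring(text, anns$start + 1L, anns$end)
}

# ---- standoff JSON ----------------------------------------------------------

#' Write annotations as standoff JSON
#'
#' One JSON object per document/set:
#' `{"doc_id", "set", "annotations": [{"id", "category", "start", "end",
#' "features": {...}}]}`.
#'
#' @param anns Annotation table for one document.
#' @param doc_id Document identifier.
#' @param set Provenance label (`"system"`, `"gold"`, `"annotatorA"`, ...).
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(anns, doc_id, set, path) {
  recs <- pmap(
    list(anns$id, anns$category, anns$start, anns$end, anns$features),
    function(id, category, start, end, features) {
      r <- list(id = id, category = category, start = start, end = end)
      if (length(features) > 0) r$features <- features
      r
    }
  )
  obj <- list(doc_id = doc_id, set = set, annotations = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a standoff JSON annotation file
#'
#' Tolerates a missing `"features"` key (treated as an empty feature map).
#'
#' @param path File written by [write_standoff()] or following the same shape.
#' @return A list with `doc_id`, `set` and `annotations` (an annotation
#'   table).
#' @export
read_standoff <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$doc_id) || is.null(obj$set)) {
    abort(paste0("not a standoff annotation file: ", path))
  }
  recs <- obj$annotations %||% list()
  anns <- annotation_tbl(
    category = map_chr(recs, "category"),
    start = map_int(recs, function(r) as.integer(r$start)),
    end = map_int(recs, function(r) as.integer(r$end)),
    features = map(recs, function(r) lapply(r$features %||% list(), identity)),
    id = map_int(recs, function(r) as.integer(r$id))
  )
  list(doc_id = obj$doc_id, set = obj$set, annotations = anns)
}

# ---- BRAT export ------------------------------------------------------------

#' Export annotations to BRAT .ann format
#'
#' Writes T-lines for spans (`T<n>\tCategory start end\tcovered text`) and
#' A-lines for boolean-valued features (`A<n>\tName T<n>`), for visual
#' inspection in BRAT-compatible viewers.  Offsets are exported unchanged
#' (BRAT also uses 0-based half-open offsets).
#'
#' @param anns Annotation table for one document.
#' @param text Document text.
#' @param path File path to write (conventionally `.ann`).
#' @return `path`, invisibly.
#' @export
write_brat <- function(anns, text, path) {
  lines <- character()
  a_n <- 0L
  for (i in seq_len(nrow(anns))) {
    tid <- paste0("T", i)
    covered <- gsub("\n", " ", substring(text, anns$start[i] + 1L, anns$end[i]))
    lines <- c(lines, paste0(
      tid, "\t", anns$category[i], " ", anns$start[i], " ", anns$end[i],
      "\t", covered
    ))
    feats <- anns$features[[i]]
    for (nm in names(feats)) {
      if (isTRUE(feats[[nm]])) {
        a_n <- a_n + 1L
        lines <- c(lines, paste0("A", a_n, "\t", nm, " ", tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- corpus container -------------------------------------------------------

#' Build a corpus table
#'
#' A corpus is a tibble with one row per report: columns `doc_id` and `text`.
#'
#' @param doc_id Character vector of unique report identifiers.
#' @param text Character vector of report texts.
#' @return A tibble.
#' @export
corpus_tbl <- function(doc_id, text) {
  stopifnot(length(doc_id) == length(text))
  if (anyDuplicated(doc_id)) abort("document ids must be unique within a corpus")
  tibble(doc_id = as.character(doc_id), text = as.character(text))
}

#' Read a corpus from a directory of .txt files or a JSON-lines file
#'
#' A directory is read one report per `.txt` file (the file stem becomes the
#' `doc_id`); a `.jsonl` file is read one `{"id": ..., "text": ...}` record
#' per line.
#'
#' @param path Directory or `.jsonl` file path.
#' @return A corpus tibble (see [corpus_tbl()]).
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("no .txt reports found under ", path))
    corpus_tbl(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, warn = FALSE), collapse = "\n")
      }, character(1))
    )
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON)
    corpus_tbl(
      doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1))
    )
  } else {
    abort(paste0("corpus path does not exist: ", path))
  }
}
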