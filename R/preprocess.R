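# Deterministic tokenisation, sentence splitting and canonical report-section
# segmentation.

#' Canonical report section labels
#'
#' The nine-part canonical structure of a BCC histopathology report.
#'
#' @return Character vector of the nine section labels.
#' @export
section_labels <- function() {
  c(
    "AccessionNumber", "ExcisionDate", "ClinicalDetails",
    "MacroscopicDetails", "MicroscopicDetails", "MicroscopicMeasurements",
    "ReportDetails", "Requestor", "SupplementaryReport"
  )
}

#' Tokenize report text
#'
#' Two policies are supported.  Under `"general"` (the pipeline default)
#' words, numbers and punctuation marks are all emitted as Token annotations
#' with a `kind` feature (`word`, `number` or `punct`); a number may carry one
#' internal decimal point.  Under `"capture"` a token is a maximal sequence of
#' alphanumeric characters delimited by spaces, slashes, brackets, braces,
#' parentheses, quotation marks or punctuation, and is kept only when it
#' begins with a letter — the token definition used for capture-probability
#' corpus sizing, which deliberately excludes numbers.
#'
#' @param text A single report text (may be empty, giving an empty table).
#' @param policy `"general"` or `"capture"`.
#'
#' @return An annotation table of category `"Token"`; under `"general"` each
#'   token has a `kind` feature.
#' @examples
#' tokenize("no residual disease.")
#' tokenize("1.2 mm", policy = "capture")  # only "mm": tokens begin with a letter
#' @export
tokenize <- function(text, policy = c("general", "capture")) {
  policy <- match.arg(policy)
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(annotation_tbl())
  if (policy == "capture") {
    m <- gregexpr("[A-Za-z0-9]+", text, perl = TRUE)[[1]]
    if (m[1] == -1) return(annotation_tbl())
    starts <- as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    toks <- substring(text, starts + 1L, ends)
    keep <- grepl("^[A-Za-z]", toks)
    return(annotation_tbl(
      category = rep("Token", sum(keep)),
      start = starts[keep], end = ends[keep]
    ))
  }
  pat <- "[A-Za-z][A-Za-z0-9]*|[0-9]+(?:\\.[0-9]+)?|[^[:space:]A-Za-z0-9]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(annotation_tbl())
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  toks <- substring(text, starts + 1L, ends)
  kind <- ifelse(
    grepl("^[A-Za-z]", toks), "word",
    ifelse(grepl("^[0-9]", toks), "number", "punct")
  )
  annotation_tbl(
    category = rep("Token", length(starts)),
    start = starts, end = ends,
    features = lapply(kind, function(k) list(kind = k))
  )
}

# Abbreviations after which a period does not end a sentence.
.sentence_abbrevs <- c("e.g", "i.e", "approx", "cf", "dr", "mr", "mrs", "ms",
                       "prof", "no", "vs")

#' Split report text into sentences
#'
#' Boundaries are placed after `.`, `?` or `!` followed by whitespace, and at
#' newline runs.  Decimal points (digit.digit), clock expressions
#' (`O'clock`), and a small abbreviation list (`e.g.`, `Dr.`, unit
#' abbreviations `cm.`/`mm.` followed by a lowercase continuation) are
#' protected.  Every non-blank stretch of text lies in exactly one Sentence.
#'
#' @param text A single report text.
#' @return An annotation table of category `"Sentence"`.
#' @examples
#' split_sentences("Nodular BCC. Completely excised.")
#' split_sentences("Diameter 1.2 mm. Clear.")  # decimal point is not a boundary
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) abort("cannot split an empty text")
  n <- nchar(text)
  chars <- strsplit(text, "")[[1]]
  # candidate hard breaks: after terminator+space, and at newlines
  breaks <- integer() # offsets AFTER which a new sentence may start (0-based end)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") {
      breaks <- c(breaks, i - 1L) # sentence ends before the newline
    } else if (ch %in% c(".", "?", "!")) {
      nxt <- if (i < n) chars[i + 1L] else " "
      if (grepl("[[:space:]]", nxt) || i == n) {
        ok <- TRUE
        if (ch == ".") {
          # decimal guard: digit on both sides never reaches here (needs space),
          # but protect abbreviation forms: word before the period in list and
          # next visible character lowercase.
          before <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, max(1L, i - 12L), i - 1L))
          word <- tolower(sub("\\.$", "", before))
          rest <- substr(text, i + 1L, min(n, i + 8L))
          nxt_vis <- sub("^[[:space:]]*", "", rest)
          if (word %in% .sentence_abbrevs && grepl("^[a-z0-9]", nxt_vis)) ok <- FALSE
          if (word %in% c("cm", "mm") && grepl("^[a-z]", nxt_vis)) ok <- FALSE
        }
        if (ok) breaks <- c(breaks, i) # sentence ends after the terminator
      }
    }
    i <- i + 1L
  }
  bounds <- sort(unique(c(0L, breaks, n)))
  starts <- head(bounds, -1L)
  ends <- tail(bounds, -1L)
  spans <- map2(starts, ends, function(s, e) {
    seg <- substring(text, s + 1L, e)
    lead <- nchar(sub("^([[:space:]]*).*$", "\\1", seg))
    trail <- nchar(sub("^.*?([[:space:]]*)$", "\\1", seg))
    c(s + lead, e - trail)
  })
  spans <- keep(spans, function(sp) sp[2] > sp[1])
  annotation_tbl(
    category = rep("Sentence", length(spans)),
    start = map_int(spans, function(sp) as.integer(sp[1])),
    end = map_int(spans, function(sp) as.integer(sp[2]))
  )
}

#' Default section-header synonym lists
#'
#' Header synonyms recognised at line start (case-insensitive, with or
#' without a trailing colon) for each canonical section.  Reports from many
#' report writers use heterogeneous headers; the list is configurable through
#' the pipeline YAML config (key `sections.headers`).
#'
#' @return Named list: section label -> character vector of header synonyms.
#' @export
default_section_headers <- function() {
  list(
    AccessionNumber = c("accession number", "accession no", "lab number",
                        "lab no", "specimen number"),
    ExcisionDate = c("excision date", "date of excision", "specimen date",
                     "date taken"),
    ClinicalDetails = c("clinical details", "clinical information",
                        "clinical history", "clinical data"),
    MacroscopicDetails = c("macroscopic details", "macroscopy",
                           "macroscopic description", "macroscopic appearance",
                           "gross description"),
    MicroscopicDetails = c("microscopic details", "microscopy",
                           "microscopic description", "histology"),
    MicroscopicMeasurements = c("microscopic measurements", "measurements",
                                "micro measurements"),
    ReportDetails = c("report details", "conclusion", "diagnosis", "comment"),
    Requestor = c("requestor", "requested by", "requesting clinician",
                  "referring clinician"),
    SupplementaryReport = c("supplementary report", "supplementary",
                            "addendum")
  )
}

#' Segment a report into canonical sections
#'
#' Each recognised header opens a Section annotation extending to the next
#' header or the end of the text.  Text before the first header is labelled
#' `ReportDetails`; a report without any recognised header yields a single
#' `ReportDetails` section spanning all text.
#'
#' @param text A single report text.
#' @param headers Named list of header synonyms, as
#'   [default_section_headers()].
#' @return An annotation table of category `"Section"`, each with a `label`
#'   feature holding the section label.
#' @export
segment_sections <- function(text, headers = default_section_headers()) {
  stopifnot(length(text) == 1, nzchar(text))
  hits <- list()
  for (label in names(headers)) {
    for (syn in headers[[label]]) {
      pat <- paste0(
        "(?mi)^[ \\t]*", gsub(" ", "[ \\\\t]+", stringr::str_escape(syn)),
        "[ \\t]*:?"
      )
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] != -1) {
        for (k in seq_along(m)) {
          hits[[length(hits) + 1L]] <- list(
            label = label,
            start = as.integer(m[k]) - 1L,
            hdr_end = as.integer(m[k]) - 1L + attr(m, "match.length")[k]
          )
        }
      }
    }
  }
  n <- nchar(text)
  if (length(hits) == 0) {
    return(annotation_tbl(
      category = "Section", start = 0L, end = n,
      features = list(list(label = "ReportDetails"))
    ))
  }
  ord <- order(map_int(hits, "start"), -map_int(hits, "hdr_end"))
  hits <- hits[ord]
  # drop shorter headers matching at the same line start
  keep_idx <- !duplicated(map_int(hits, "start"))
  hits <- hits[keep_idx]
  starts <- map_int(hits, "start")
  labels <- map_chr(hits, "label")
  sec_start <- starts
  sec_end <- c(starts[-1], n)
  out_start <- integer()
  out_end <- integer()
  out_label <- character()
  if (starts[1] > 0 && nzchar(trimws(substr(text, 1, starts[1])))) {
    out_start <- 0L
    out_end <- starts[1]
    out_label <- "ReportDetails"
  }
  out_start <- c(out_start, sec_start)
  out_end <- c(out_end, sec_end)
  out_label <- c(out_label, labels)
  annotation_tbl(
    category = rep("Section", length(out_start)),
    start = out_start, end = out_end,
    features = lapply(out_label, function(l) list(label = l))
  )
}
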