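# Measurement-phrase parsing: "<num> mm|cm", dimension triplets
# "15 x 8 x 4 mm", qualifiers ("less than", "<"), clock positions
# ("at 12 O'clock").  All values are normalised to millimetres.

.qualifier_pats <- c(
  less_than = "less\\s+than|<",
  greater_than = "greater\\s+than|more\\s+than|>(?!=)",
  at_least = "at\\s+least|>=|≥"
)

#' Parse a measurement phrase
#'
#' Recognises single values (`"1 mm"`, `"0.5 cm"`), dimension products
#' (`"15 x 8 x 4 mm"` — the unit distributes over all dimensions), numeric
#' qualifiers (`"less than 1 mm"`, `"<1 mm"`, `"at least 2 mm"`) and clock
#' positions (`"at 12 O'clock"`, case and punctuation tolerant).  Centimetre
#' values are multiplied by 10 into millimetres.  A phrase without a
#' parseable numeric (e.g. `"a few mm"`) yields an empty result with an
#' informative message, never an error.
#'
#' @param text The measurement phrase.
#' @param axis Optional axis hint: one of `peripheral`, `deep`, `thickness`,
#'   `diameter`; dimension products are always labelled `dim1`..`dim3`.
#'   When `NULL`, axis keywords in the phrase itself are used.
#'
#' @return A tibble with columns `value` (mm), `unit` (`"mm"`), `qualifier`,
#'   `clock`, `axis`; zero rows when nothing parses.
#' @examples
#' parse_measurement("peripheral clearance 1 mm at 12 O'clock")
#' parse_measurement("15 x 8 x 4 mm")
#' parse_measurement("0.5 cm")  # 5 mm
#' @export
parse_measurement <- function(text, axis = NULL) {
  stopifnot(length(text) == 1, nzchar(text))
  out <- tibble(
    value = numeric(), unit = character(), qualifier = character(),
    clock = integer(), axis = character()
  )
  low <- tolower(text)

  clock <- NA_integer_
  cm <- stringr::str_match(low, "at\\s+(\\d{1,2})\\s*o\\W{0,2}clock")
  if (!is.na(cm[1, 1])) {
    cl <- as.integer(cm[1, 2])
    if (cl >= 1 && cl <= 12) clock <- cl
  }

  qualifier <- "exact"
  for (q in names(.qualifier_pats)) {
    if (grepl(.qualifier_pats[[q]], low, perl = TRUE)) {
      qualifier <- q
      break
    }
  }

  axis_hint <- axis
  if (is.null(axis_hint)) {
    axis_hint <- if (grepl("peripheral", low)) "peripheral"
    else if (grepl("deep", low)) "deep"
    else if (grepl("thickness|thick", low)) "thickness"
    else if (grepl("diameter", low)) "diameter"
    else NA_character_
  }

  num <- "(\\d+(?:\\.\\d+)?)"
  dims <- stringr::str_match(
    low,
    paste0(num, "\\s*[x×]\\s*", num, "(?:\\s*[x×]\\s*", num, ")?\\s*(mm|cm)")
  )
  if (!is.na(dims[1, 1])) {
    vals <- as.numeric(dims[1, 2:4])
    vals <- vals[!is.na(vals)]
    unit <- dims[1, 5]
    if (unit == "cm") vals <- vals * 10
    return(tibble(
      value = vals, unit = "mm", qualifier = qualifier,
      clock = clock, axis = paste0("dim", seq_along(vals))
    ))
  }

  single <- stringr::str_match(low, paste0(num, "\\s*(mm|cm)\\b"))
  if (!is.na(single[1, 1])) {
    val <- as.numeric(single[1, 2])
    if (single[1, 3] == "cm") val <- val * 10
    return(tibble(
      value = val, unit = "mm", qualifier = qualifier,
      clock = clock, axis = axis_hint %||% NA_character_
    ))
  }

  inform(paste0("no parseable measurement in: '", text, "'"),
         class = "bccner_unparseable_measurement")
  out
}

#' The shipped BCC extraction schema
#'
#' Nine entity categories aligned with the canonical report sections, each
#' with named feature definitions (value kinds: text, number in mm, date,
#' boolean, clock position).  Loaded from YAML; the schema is closed — a
#' config declaring unknown features is rejected.
#'
#' @param path Schema YAML file; defaults to the schema shipped with the
#'   package.
#' @return A `bcc_schema` object: named list category -> tibble of features
#'   (`feature`, `kind`).
#' @export
read_schema <- function(path = system.file("extdata", "bcc", "schema.yaml",
                                           package = "bccner")) {
  y <- yaml::read_yaml(path)
  if (is.null(y$categories)) abort(paste0(path, ": schema lacks 'categories'"))
  kinds <- c("text", "number", "date", "boolean", "clock")
  cats <- lapply(y$categories, function(cat) {
    feats <- cat$features %||% list()
    tb <- tibble(
      feature = map_chr(feats, "name"),
      kind = map_chr(feats, function(f) f$kind %||% "text")
    )
    bad <- setdiff(tb$kind, kinds)
    if (length(bad) > 0) {
      abort(paste0(path, ": unknown feature kind(s): ", paste(bad, collapse = ", ")))
    }
    tb
  })
  names(cats) <- map_chr(y$categories, "name")
  unknown <- setdiff(names(cats), section_labels())
  if (length(unknown) > 0) {
    abort(paste0(path, ": unknown categories: ", paste(unknown, collapse = ", ")))
  }
  all_feats <- unlist(lapply(cats, function(tb) tb$feature))
  if (anyDuplicated(all_feats)) {
    abort(paste0(
      path, ": features must belong to exactly one category; duplicated: ",
      paste(unique(all_feats[duplicated(all_feats)]), collapse = ", ")
    ))
  }
  structure(cats, class = "bcc_schema")
}

#' @export
print.bcc_schema <- function(x, ...) {
  cat("<bcc_schema> ", length(x), " categories, ",
      sum(map_int(x, nrow)), " features\n", sep = "")
  invisible(x)
}

#' Flat list of schema record columns, in schema declaration order
#'
#' @param schema A `bcc_schema`.
#' @return Character vector of feature names.
#' @export
schema_features <- function(schema) {
  unlist(lapply(unclass(schema), function(tb) tb$feature), use.names = FALSE)
}
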