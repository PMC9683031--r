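# ConText-style negation/affirmation detection.  Triggers open a scope in
# their direction; the scope closes at the first termination term, the
# sentence boundary, or an optional token-window cap.  Targets wholly inside
# a negation scope get negated=TRUE; inside an affirmation scope,
# affirmed=TRUE.  Trigger matching reuses the gazetteer longest-match
# scanner.

#' Read a ConText trigger lexicon
#'
#' Same tab-separated format as gazetteers, with `majorType = context` and
#' `minorType = category:direction` where category is one of `negation`,
#' `affirmation`, `pseudo`, `termination` and direction one of `forward`,
#' `backward`, `bidirectional` (defaulting to `forward`; pseudo and
#' termination triggers need no direction).
#'
#' @param path Trigger lexicon file.
#' @return A tibble with columns `term`, `category`, `direction`.
#' @export
read_triggers <- function(path) {
  g <- read_gazetteer(path)
  parts <- strsplit(ifelse(is.na(g$minorType), "", g$minorType), ":", fixed = TRUE)
  cat <- map_chr(parts, function(p) if (length(p) >= 1 && nzchar(p[1])) p[1] else NA_character_)
  dir <- map_chr(parts, function(p) if (length(p) >= 2) p[2] else "forward")
  bad <- is.na(cat) | !cat %in% c("negation", "affirmation", "pseudo", "termination")
  if (any(bad)) {
    abort(paste0(
      "invalid trigger categories in ", path, ": ",
      paste(unique(g$term[bad]), collapse = ", ")
    ))
  }
  tibble(term = g$term, category = cat, direction = dir)
}

#' Apply ConText negation/affirmation to target annotations
#'
#' @param text Document text.
#' @param anns Annotation table containing `Sentence` annotations and the
#'   target annotations.
#' @param targets Character vector of target category names.
#' @param triggers Trigger tibble from [read_triggers()] (columns `term`,
#'   `category`, `direction`).
#' @param window_tokens Optional cap on scope length in tokens from the
#'   trigger (default unlimited; the scope is always sentence-bounded).
#'
#' @return `anns` with `negated = TRUE` / `affirmed = TRUE` features set on
#'   in-scope targets.  An annotation caught by both polarities keeps only
#'   `negated` (negation takes precedence, so the two are never both true).
#' @examples
#' anns <- annotation_tbl("ResidualDisease", 13L, 29L)
#' anns <- dplyr::bind_rows(anns, annotation_tbl("Sentence", 0L, 29L, id = 2L))
#' trig <- tibble::tibble(term = "no", category = "negation", direction = "forward")
#' out <- apply_context("there was no residual disease", anns, "ResidualDisease", trig)
#' @export
apply_context <- function(text, anns, targets, triggers, window_tokens = Inf) {
  sentences <- ann_select(anns, "Sentence")
  if (nrow(sentences) == 0) abort("apply_context needs Sentence annotations")
  tgt_rows <- which(anns$category %in% targets)
  if (length(tgt_rows) == 0 || nrow(triggers) == 0) return(anns)

  trig_entries <- tibble(
    term = triggers$term,
    majorType = "context",
    minorType = paste0(triggers$category, ":", triggers$direction),
    conceptCode = NA_character_,
    caseSensitive = FALSE,
    gazetteer = "context"
  )
  index <- compile_gazetteer(trig_entries)
  tokens <- tokenize(text)
  hits <- scan_index(text, tokens, index)
  if (nrow(hits) == 0) return(anns)
  hits$category <- triggers$category[hits$entry_row]
  hits$direction <- triggers$direction[hits$entry_row]
  # pseudo-trigger suppression: a pseudo match blocks any trigger at its start
  pseudo_starts <- hits$start[hits$category == "pseudo"]
  hits <- hits[!(hits$start %in% pseudo_starts), , drop = FALSE]
  term_hits <- hits[hits$category == "termination", , drop = FALSE]
  polar <- hits[hits$category %in% c("negation", "affirmation"), , drop = FALSE]
  if (nrow(polar) == 0) return(anns)

  negated <- logical(nrow(anns))
  affirmed <- logical(nrow(anns))
  for (k in seq_len(nrow(polar))) {
    trig <- polar[k, ]
    sent <- sentences[sentences$start <= trig$start & trig$end <= sentences$end, ]
    if (nrow(sent) == 0) next
    sent <- sent[1, ]
    scopes <- list()
    if (trig$direction %in% c("forward", "bidirectional")) {
      lo <- trig$end
      hi <- sent$end
      after <- term_hits$start[term_hits$start >= trig$end & term_hits$start < hi]
      if (length(after) > 0) hi <- min(after)
      if (is.finite(window_tokens)) {
        in_scope <- tokens[tokens$start >= lo & tokens$end <= sent$end, ]
        if (nrow(in_scope) > window_tokens) {
          hi <- min(hi, in_scope$end[window_tokens])
        }
      }
      if (hi > lo) scopes[[length(scopes) + 1L]] <- c(lo, hi)
    }
    if (trig$direction %in% c("backward", "bidirectional")) {
      lo <- sent$start
      hi <- trig$start
      before <- term_hits$end[term_hits$end <= trig$start & term_hits$end > lo]
      if (length(before) > 0) lo <- max(before)
      if (is.finite(window_tokens)) {
        in_scope <- tokens[tokens$start >= sent$start & tokens$end <= hi, ]
        if (nrow(in_scope) > window_tokens) {
          lo <- max(lo, in_scope$start[nrow(in_scope) - window_tokens + 1L])
        }
      }
      if (hi > lo) scopes[[length(scopes) + 1L]] <- c(lo, hi)
    }
    for (sc in scopes) {
      inside <- tgt_rows[anns$start[tgt_rows] >= sc[1] & anns$end[tgt_rows] <= sc[2]]
      if (trig$category == "negation") negated[inside] <- TRUE else affirmed[inside] <- TRUE
    }
  }
  affirmed <- affirmed & !negated # negation takes precedence
  for (i in which(negated)) anns$features[[i]]$negated <- TRUE
  for (i in which(affirmed)) anns$features[[i]]$affirmed <- TRUE
  anns
}
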