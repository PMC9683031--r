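# Published reference tallies for a rule-based BCC extraction system
# evaluated against clinician annotation on a 41-report training corpus and
# a 200-report validation corpus, shipped as a worked-example fixture for
# the scoring machinery.

#' Reference evaluation tallies
#'
#' Per-entity annotation and alignment tallies (match / missing / spurious /
#' partial, with clinician and algorithm annotation totals) reported for a
#' rule-based BCC histopathology extraction system on its training and
#' validation corpora.  Useful as a worked example for [score_counts()]:
#' fixed-format fields (accession number, excision date, requestor) score
#' 100% under the lenient scheme.
#'
#' A handful of printed cells are internally inconsistent with the count
#' identities `clinician = match + missing + partial` and
#' `algorithm = match + spurious + partial`; [tally_identity_check()] flags
#' them.  The tallies are shipped exactly as printed.
#'
#' @return A tibble, one row per (entity, corpus).
#' @export
bcc_reference_tallies <- function() {
  path <- system.file("extdata", "eval", "reference_tallies.csv", package = "bccner")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Check the count identities of reference tallies
#'
#' For every row, checks `clinician_annotations = match + missing + partial`
#' (key side) and `algorithm_annotations = match + spurious + partial`
#' (response side).
#'
#' @param tallies Tibble from [bcc_reference_tallies()] (or the same shape).
#' @return The tallies with logical columns `key_identity`,
#'   `response_identity` and the signed discrepancies `key_delta`,
#'   `response_delta`.
#' @export
tally_identity_check <- function(tallies = bcc_reference_tallies()) {
  tallies |>
    mutate(
      key_total = .data$match + .data$missing + .data$partial,
      response_total = .data$match + .data$spurious + .data$partial,
      key_delta = .data$key_total - .data$clinician_annotations,
      response_delta = .data$response_total - .data$algorithm_annotations,
      key_identity = .data$key_delta == 0L,
      response_identity = .data$response_delta == 0L
    )
}

#' Score reference tallies under a matching scheme
#'
#' @param tallies Tibble from [bcc_reference_tallies()].
#' @param scheme Matching scheme, see [score_counts()].
#' @return The tallies with `precision`, `recall`, `f1` columns (percent).
#' @export
score_tallies <- function(tallies = bcc_reference_tallies(),
                          scheme = c("lenient", "average", "strict")) {
  scheme <- match.arg(scheme)
  scores <- pmap(
    list(tallies$match, tallies$partial, tallies$missing, tallies$spurious),
    function(m, p, mi, s) score_counts(eval_counts(m, p, mi, s), scheme)
  ) |> list_rbind()
  tallies |>
    mutate(
      precision = 100 * scores$precision,
      recall = 100 * scores$recall,
      f1 = 100 * scores$f1
    )
}
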