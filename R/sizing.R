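# Validation-corpus sizing by token capture probability: the chance that a
# uniform without-replacement sample of N documents contains at least one
# document bearing a concept token, hypergeometric and computed in log space.

#' Capture probability of one token
#'
#' For a token present in `d` of `D` corpus documents, the probability that
#' a uniform without-replacement sample of `N` documents contains at least
#' one of them: `1 - C(D - d, N) / C(D, N)`, evaluated via log binomial
#' coefficients so large corpora stay stable.  Vectorised over `d`.
#'
#' @param d Document frequency (1 <= d <= D).
#' @param D Corpus size.
#' @param N Sample size (0 <= N <= D).
#' @return Probability in \[0, 1\].
#' @examples
#' capture_probability(5, 10, 2) # 1 - C(5,2)/C(10,2) = 0.7777...
#' @export
capture_probability <- function(d, D, N) {
  stopifnot(length(D) == 1, length(N) == 1)
  if (N > D) abort("sample size N cannot exceed corpus size D")
  if (N < 0) abort("sample size N must be non-negative")
  if (any(d < 1) || any(d > D)) abort("document frequency must satisfy 1 <= d <= D")
  if (N == 0) return(rep(0, length(d)))
  p_miss <- ifelse(D - d < N, 0, exp(lchoose(D - d, N) - lchoose(D, N)))
  1 - p_miss
}

#' Corpus-level capture estimate
#'
#' Aggregates per-token capture probabilities over the concept-token
#' vocabulary.  The default aggregation is the mean per-token probability;
#' the alternative reports the fraction of tokens whose individual capture
#' probability reaches `threshold`.
#'
#' @param freq Frequency tibble with columns `token` and `doc_frequency`
#'   (see [token_doc_frequency()]); an optional `corpus_size` column must be
#'   constant.
#' @param N Sample size.
#' @param D Corpus size; taken from `freq$corpus_size` when present.
#' @param aggregation `"mean"` or `"fraction"`.
#' @param threshold Per-token probability threshold for `"fraction"`.
#' @return A `bcc_capture` object: `sample_size`, `overall`, `per_token`
#'   tibble, plus the aggregation used.
#' @export
corpus_capture <- function(freq, N, D = NULL,
                           aggregation = c("mean", "fraction"),
                           threshold = 0.9) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(freq), nrow(freq) > 0,
            all(c("token", "doc_frequency") %in% names(freq)))
  if ("corpus_size" %in% names(freq)) {
    sizes <- unique(freq$corpus_size)
    if (length(sizes) != 1) abort("inconsistent corpus_size values in frequency table")
    if (!is.null(D) && D != sizes) abort("corpus_size column disagrees with D")
    D <- sizes
  }
  if (is.null(D)) abort("corpus size D required (argument or corpus_size column)")
  p <- capture_probability(freq$doc_frequency, D, N)
  overall <- if (aggregation == "mean") mean(p) else mean(p >= threshold)
  structure(
    list(
      sample_size = N, corpus_size = D, overall = overall,
      aggregation = aggregation,
      threshold = if (aggregation == "fraction") threshold else NA_real_,
      per_token = tibble(token = freq$token, doc_frequency = freq$doc_frequency,
                         capture = p)
    ),
    class = "bcc_capture"
  )
}

#' @export
print.bcc_capture <- function(x, ...) {
  cat(sprintf(
    "<bcc_capture> N=%d of D=%d: overall %.1f%% (%s aggregation, %d tokens)\n",
    x$sample_size, x$corpus_size, 100 * x$overall, x$aggregation,
    nrow(x$per_token)
  ))
  invisible(x)
}

#' Smallest sample size reaching a target capture probability
#'
#' The overall capture probability is non-decreasing in `N` (each token's
#' hypergeometric capture probability is), so the smallest `N` with
#' `corpus_capture(freq, N) >= target` is found by binary search over
#' `0..D`.
#'
#' @inheritParams corpus_capture
#' @param target Target overall capture probability, in (0, 1].
#' @return The minimal sample size `N` (integer).
#' @export
min_sample_size <- function(freq, target, D = NULL,
                            aggregation = c("mean", "fraction"),
                            threshold = 0.9) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(target) == 1, target > 0, target <= 1)
  probe <- function(N) {
    corpus_capture(freq, N, D = D, aggregation = aggregation,
                   threshold = threshold)$overall
  }
  full <- corpus_capture(freq, 1, D = D, aggregation = aggregation,
                         threshold = threshold)
  Dval <- full$corpus_size
  if (probe(Dval) < target) {
    abort("target capture probability unreachable even sampling the whole corpus")
  }
  lo <- 0L
  hi <- as.integer(Dval) # invariant: probe(hi) >= target > probe(lo) unless lo=0 works
  if (probe(0L) >= target) return(0L)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (probe(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Concept-token document frequencies for a corpus
#'
#' Tokenises every document under the `"capture"` token policy (maximal
#' alphanumeric sequences beginning with a letter) and counts, for each
#' token of the concept vocabulary, the number of documents containing it.
#' The vocabulary is the set of capture-policy tokens of the supplied
#' concept terms; concept tokens absent from the corpus are dropped with a
#' message (a capture probability needs `d >= 1`).
#'
#' @param corpus Corpus tibble (`doc_id`, `text`).
#' @param concepts Character vector of concept terms (multi-word terms are
#'   tokenised; their tokens pooled into one vocabulary).
#' @return Tibble: `token`, `doc_frequency`, `corpus_size`.
#' @export
token_doc_frequency <- function(corpus, concepts) {
  stopifnot(is.data.frame(corpus), nrow(corpus) > 0, length(concepts) > 0)
  vocab <- unique(unlist(lapply(concepts, function(tm) {
    toks <- tokenize(tm, policy = "capture")
    tolower(covered_text(toks, tm))
  })))
  vocab <- vocab[nzchar(vocab)]
  doc_tokens <- lapply(corpus$text, function(tx) {
    toks <- tokenize(tx, policy = "capture")
    unique(tolower(covered_text(toks, tx)))
  })
  dfreq <- vapply(vocab, function(v) {
    sum(vapply(doc_tokens, function(dt) v %in% dt, logical(1)))
  }, integer(1))
  absent <- vocab[dfreq == 0]
  if (length(absent) > 0) {
    inform(paste0(
      "concept tokens absent from the corpus dropped: ",
      paste(head(absent, 10), collapse = ", "),
      if (length(absent) > 10) ", ..." else ""
    ))
  }
  tibble(
    token = vocab[dfreq > 0],
    doc_frequency = unname(dfreq[dfreq > 0]),
    corpus_size = nrow(corpus)
  )
}
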