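# broom-style tidiers and ggplot2 autoplot methods for fitted/evaluated
# objects.

#' @method tidy bcc_eval
#' @export
tidy.bcc_eval <- function(x, aggregation = x$aggregation, ...) {
  if (aggregation == "macro") {
    x$macro
  } else {
    select(x$micro, "category", "scheme", "precision", "recall", "f1")
  }
}

#' @method glance bcc_eval
#' @export
glance.bcc_eval <- function(x, ...) {
  ov <- if (x$aggregation == "macro") {
    x$macro_overall
  } else {
    mutate(select(x$micro_overall, -"scheme"), n_docs = x$n_documents)
  }
  mutate(ov,
    scheme = x$scheme, aggregation = x$aggregation,
    n_documents = x$n_documents
  )
}

#' @method tidy bcc_capture
#' @export
tidy.bcc_capture <- function(x, ...) {
  x$per_token
}

#' @method glance bcc_capture
#' @export
glance.bcc_capture <- function(x, ...) {
  tibble(
    sample_size = x$sample_size, corpus_size = x$corpus_size,
    overall = x$overall, aggregation = x$aggregation,
    n_tokens = nrow(x$per_token)
  )
}

#' Per-category score plot for a corpus evaluation
#'
#' Dot-and-interval plot of per-category precision, recall and F1 (macro
#' aggregation shows the 95% confidence interval over per-document scores).
#'
#' @param object A `bcc_eval` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcc_eval
#' @export
autoplot.bcc_eval <- function(object, ...) {
  td <- tidy(object, aggregation = "macro")
  long <- tidyr::pivot_longer(
    td,
    cols = c("precision", "recall", "f1"),
    names_to = "measure", values_to = "score"
  )
  long$lo <- dplyr::case_when(
    long$measure == "precision" ~ td$precision_lo[match(long$category, td$category)],
    long$measure == "recall" ~ td$recall_lo[match(long$category, td$category)],
    TRUE ~ td$f1_lo[match(long$category, td$category)]
  )
  long$hi <- dplyr::case_when(
    long$measure == "precision" ~ td$precision_hi[match(long$category, td$category)],
    long$measure == "recall" ~ td$recall_hi[match(long$category, td$category)],
    TRUE ~ td$f1_hi[match(long$category, td$category)]
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$score, y = .data$category, colour = .data$measure
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = "score (per-document mean, 95% CI)", y = NULL,
      colour = NULL,
      title = paste0("Extraction performance (", object$scheme, " matching)")
    ) +
    ggplot2::theme_minimal()
}

#' Capture-probability curve
#'
#' Overall capture probability as a function of validation-sample size, for
#' choosing the number of documents in a gold-standard corpus.
#'
#' @param object A `bcc_capture` from [corpus_capture()].
#' @param freq The frequency table the estimate was built from (needed to
#'   sweep sample sizes).
#' @param target Optional target probability drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bcc_capture
#' @export
autoplot.bcc_capture <- function(object, freq, target = NULL, ...) {
  D <- object$corpus_size
  Ns <- unique(round(seq(0, D, length.out = min(D + 1, 101))))
  curve <- tibble(
    N = Ns,
    overall = vapply(Ns, function(N) {
      corpus_capture(freq, N, D = D, aggregation = object$aggregation,
                     threshold = if (is.na(object$threshold)) 0.9 else object$threshold)$overall
    }, numeric(1))
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$N, y = .data$overall)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "validation sample size (documents)",
      y = "overall capture probability"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    p <- p + ggplot2::geom_hline(yintercept = target, linetype = "dashed")
  }
  p
}
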