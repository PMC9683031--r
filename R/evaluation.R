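# Scoring machinery: key/response alignment into correct/partial/missing/
# spurious tallies, strict/average/lenient precision-recall-F1, per-document
# macro averaging with normal-approximation confidence intervals, token-level
# confusion, Cohen's kappa, positive specific agreement and pairwise F1.

#' Alignment tallies
#'
#' @param correct Coextensive, feature-compatible pairs.
#' @param partial Overlapping (not coextensive), feature-compatible pairs.
#' @param missing Unmatched key annotations.
#' @param spurious Unmatched response annotations.
#' @return An `eval_counts` object.  Key total = correct + partial + missing;
#'   response total = correct + partial + spurious.
#' @export
eval_counts <- function(correct = 0, partial = 0, missing = 0, spurious = 0) {
  vals <- c(correct = correct, partial = partial, missing = missing, spurious = spurious)
  if (any(is.na(vals)) || any(vals < 0)) abort("eval counts must be non-negative")
  structure(as.list(vals), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat("<eval_counts> correct=", x$correct, " partial=", x$partial,
      " missing=", x$missing, " spurious=", x$spurious, "\n", sep = "")
  invisible(x)
}

add_counts <- function(a, b) {
  eval_counts(
    a$correct + b$correct, a$partial + b$partial,
    a$missing + b$missing, a$spurious + b$spurious
  )
}

norm_feature_value <- function(v) {
  if (is.numeric(v)) return(as.character(v))
  tolower(trimws(gsub("[[:space:]]+", " ", as.character(v))))
}

# Every key feature must be present in the response with an equal normalized
# value (inclusion runs from key into response; extra response features are
# fine).  The auxiliary `section` feature is ignored.
features_compatible <- function(key_f, resp_f) {
  for (nm in setdiff(names(key_f), "section")) {
    rv <- resp_f[[nm]]
    if (is.null(rv)) return(FALSE)
    if (!identical(norm_feature_value(key_f[[nm]]), norm_feature_value(rv))) {
      return(FALSE)
    }
  }
  TRUE
}

# Minimum-cost assignment on a square cost matrix (Jonker-Volgenant style
# potentials, O(n^3)); returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row assigned to column j (0 = virtual column)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Align a key and a response annotation set
#'
#' Optimal pairing: each annotation is used at most once, coextensive
#' feature-compatible pairs are preferred over merely overlapping ones, and
#' among pairings with the most coextensive (correct) pairs the one with the
#' most overlapping (partial) pairs is chosen — an exact maximum-weight
#' assignment, so the tallies agree with exhaustive enumeration.  Feature
#' compatibility means every key feature is present in the response with an
#' equal normalized value.  Leftovers are counted missing (key) and spurious
#' (response).
#'
#' @param key,response Annotation tables over the same document.
#' @param category Optional category filter.
#' @return An [eval_counts()] object.
#' @export
align_annotations <- function(key, response, category = NULL) {
  k <- ann_select(key, category = category)
  r <- ann_select(response, category = category)
  nk <- nrow(k)
  nr <- nrow(r)
  if (nk == 0 || nr == 0) {
    return(eval_counts(missing = nk, spurious = nr))
  }
  n <- max(nk, nr)
  W <- n + 2 # dominates any attainable number of partial pairs
  B <- matrix(0, n, n)
  for (i in seq_len(nk)) {
    for (j in seq_len(nr)) {
      if (k$category[i] != r$category[j]) next
      if (k$start[i] >= r$end[j] || r$start[j] >= k$end[i]) next
      if (!features_compatible(k$features[[i]], r$features[[j]])) next
      coext <- k$start[i] == r$start[j] && k$end[i] == r$end[j]
      B[i, j] <- if (coext) W else 1
    }
  }
  correct <- 0L
  partial <- 0L
  if (any(B > 0)) {
    assign <- solve_assignment(max(B) - B)
    for (i in seq_len(nk)) {
      j <- assign[i]
      if (j >= 1 && j <= nr) {
        if (B[i, j] == W) correct <- correct + 1L
        else if (B[i, j] == 1) partial <- partial + 1L
      }
    }
  }
  eval_counts(
    correct = correct, partial = partial,
    missing = nk - correct - partial, spurious = nr - correct - partial
  )
}

scheme_weight <- function(scheme = c("lenient", "average", "strict")) {
  switch(match.arg(scheme), strict = 0, average = 0.5, lenient = 1)
}

#' Score alignment tallies under a matching scheme
#'
#' Precision `= (correct + w * partial) / (correct + spurious + partial)` and
#' recall `= (correct + w * partial) / (correct + missing + partial)` with
#' partial weight `w` 0 (strict), 1/2 (average) or 1 (lenient); F1 is the
#' harmonic mean.  An empty denominator scores 1 when the other side is also
#' empty (correctly extracting nothing), else 0.
#'
#' @param counts An [eval_counts()] object.
#' @param scheme `"lenient"` (default), `"average"` or `"strict"`.
#' @return One-row tibble: `scheme`, `precision`, `recall`, `f1` (proportions
#'   in \[0, 1\]).
#' @export
score_counts <- function(counts, scheme = c("lenient", "average", "strict")) {
  scheme <- match.arg(scheme)
  w <- scheme_weight(scheme)
  num <- counts$correct + w * counts$partial
  p_den <- counts$correct + counts$spurious + counts$partial
  r_den <- counts$correct + counts$missing + counts$partial
  p <- if (p_den > 0) num / p_den else if (r_den == 0) 1 else 0
  r <- if (r_den > 0) num / r_den else if (p_den == 0) 1 else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(scheme = scheme, precision = p, recall = r, f1 = f1)
}

ci_bounds <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) sd(x) else 0
  half <- qnorm(0.975) * s / sqrt(n)
  c(m, max(0, m - half), min(1, m + half))
}

#' Evaluate a corpus: per-category and overall scores with 95% CIs
#'
#' Macro aggregation averages per-document scores (normal-approximation 95%
#' confidence intervals over the per-document score distribution); micro
#' aggregation scores the summed tallies.  Both are computed; `aggregation`
#' selects which one [tidy()] and [glance()] report.  For a category, a
#' document contributes a score when either set mentions the category.
#' Documents missing one of the two annotation sets entirely are listed in a
#' warning and skipped.
#'
#' @param annotations Corpus-level annotation tibble with columns `doc_id`,
#'   `set`, `category`, `start`, `end`, `features`.
#' @param key,response Provenance labels of the key (gold) and response
#'   (system) sets.
#' @param scheme Matching scheme, see [score_counts()].
#' @param aggregation `"macro"` (default) or `"micro"`.
#' @return A `bcc_eval` object.
#' @export
evaluate_corpus <- function(annotations, key = "gold", response = "system",
                            scheme = c("lenient", "average", "strict"),
                            aggregation = c("macro", "micro")) {
  scheme <- match.arg(scheme)
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(annotations), all(c("doc_id", "set") %in% names(annotations)))
  docs <- unique(annotations$doc_id)
  have_key <- unique(annotations$doc_id[annotations$set == key])
  have_resp <- unique(annotations$doc_id[annotations$set == response])
  lacking <- setdiff(docs, intersect(have_key, have_resp))
  usable <- intersect(have_key, have_resp)
  if (length(lacking) > 0) {
    warn(paste0(
      "documents lacking a '", key, "' or '", response, "' set skipped: ",
      paste(lacking, collapse = ", ")
    ))
  }
  if (length(usable) == 0) abort("no documents carry both annotation sets")
  cats <- sort(unique(annotations$category[annotations$set %in% c(key, response)]))
  doc_scores <- list()
  micro_counts <- list()
  doc_overall <- numeric(0)
  overall_rows <- list()
  for (d in usable) {
    kset <- annotations[annotations$doc_id == d & annotations$set == key, , drop = FALSE]
    rset <- annotations[annotations$doc_id == d & annotations$set == response, , drop = FALSE]
    total <- eval_counts()
    for (cat in cats) {
      if (!cat %in% kset$category && !cat %in% rset$category) next
      cnt <- align_annotations(kset, rset, category = cat)
      total <- add_counts(total, cnt)
      micro_counts[[cat]] <- if (is.null(micro_counts[[cat]])) cnt else add_counts(micro_counts[[cat]], cnt)
      sc <- score_counts(cnt, scheme)
      doc_scores[[length(doc_scores) + 1L]] <- mutate(sc, doc_id = d, category = cat)
    }
    sco <- score_counts(total, scheme)
    overall_rows[[length(overall_rows) + 1L]] <- mutate(sco, doc_id = d)
  }
  per_doc <- list_rbind(doc_scores)
  macro_cat <- per_doc |>
    group_by(.data$category) |>
    summarise(
      n_docs = n(),
      p = list(ci_bounds(.data$precision)),
      r = list(ci_bounds(.data$recall)),
      f = list(ci_bounds(.data$f1)),
      .groups = "drop"
    ) |>
    mutate(
      precision = map_dbl(.data$p, 1), precision_lo = map_dbl(.data$p, 2), precision_hi = map_dbl(.data$p, 3),
      recall = map_dbl(.data$r, 1), recall_lo = map_dbl(.data$r, 2), recall_hi = map_dbl(.data$r, 3),
      f1 = map_dbl(.data$f, 1), f1_lo = map_dbl(.data$f, 2), f1_hi = map_dbl(.data$f, 3)
    ) |>
    select(-"p", -"r", -"f")
  od <- list_rbind(overall_rows)
  macro_overall <- tibble(
    n_docs = nrow(od),
    precision = ci_bounds(od$precision)[1],
    precision_lo = ci_bounds(od$precision)[2],
    precision_hi = ci_bounds(od$precision)[3],
    recall = ci_bounds(od$recall)[1],
    recall_lo = ci_bounds(od$recall)[2],
    recall_hi = ci_bounds(od$recall)[3],
    f1 = ci_bounds(od$f1)[1],
    f1_lo = ci_bounds(od$f1)[2],
    f1_hi = ci_bounds(od$f1)[3]
  )
  micro_cat <- list_rbind(imap(micro_counts, function(cnt, cat) {
    mutate(score_counts(cnt, scheme), category = cat)
  }))
  micro_total <- Reduce(add_counts, micro_counts, eval_counts())
  structure(
    list(
      scheme = scheme, aggregation = aggregation,
      per_document = per_doc,
      macro = macro_cat, macro_overall = macro_overall,
      micro = micro_cat, micro_overall = score_counts(micro_total, scheme),
      micro_counts = micro_counts,
      n_documents = length(usable), skipped = lacking
    ),
    class = "bcc_eval"
  )
}

#' @export
print.bcc_eval <- function(x, ...) {
  ov <- if (x$aggregation == "macro") x$macro_overall else x$micro_overall
  cat("<bcc_eval> ", x$n_documents, " documents, scheme=", x$scheme,
      ", aggregation=", x$aggregation, "\n", sep = "")
  cat(sprintf(
    "  overall P=%.1f%% R=%.1f%% F1=%.1f%%\n",
    100 * ov$precision, 100 * ov$recall, 100 * ov$f1
  ))
  invisible(x)
}

#' Pairwise F1 between two annotation sets
#'
#' Scores `b` against `a` as key, and the role-swapped direction; under the
#' lenient and average schemes swapping roles exchanges precision and recall,
#' so the two F1 values agree.  Per-category F1 in both directions is
#' returned alongside.
#'
#' @param a,b Annotation tables over the same document (or corpus-level
#'   tables with a `doc_id` column covering the same documents).
#' @param scheme Matching scheme.
#' @return List: `f1` (a as key), `f1_swapped`, `per_category` tibble.
#' @export
pairwise_f1 <- function(a, b, scheme = c("lenient", "average", "strict")) {
  scheme <- match.arg(scheme)
  if (!"doc_id" %in% names(a)) a$doc_id <- "doc"
  if (!"doc_id" %in% names(b)) b$doc_id <- "doc"
  cats <- sort(unique(c(a$category, b$category)))
  docs <- unique(c(a$doc_id, b$doc_id))
  per_cat <- list()
  tot_ab <- eval_counts()
  for (cat in cats) {
    cnt <- eval_counts()
    for (d in docs) {
      cnt <- add_counts(cnt, align_annotations(
        a[a$doc_id == d, , drop = FALSE],
        b[b$doc_id == d, , drop = FALSE],
        category = cat
      ))
    }
    tot_ab <- add_counts(tot_ab, cnt)
    swapped <- eval_counts(cnt$correct, cnt$partial, cnt$spurious, cnt$missing)
    per_cat[[length(per_cat) + 1L]] <- tibble(
      category = cat,
      f1 = score_counts(cnt, scheme)$f1,
      f1_swapped = score_counts(swapped, scheme)$f1
    )
  }
  per_category <- list_rbind(per_cat)
  per_category$difference <- per_category$f1 - per_category$f1_swapped
  tot_ba <- eval_counts(tot_ab$correct, tot_ab$partial, tot_ab$spurious, tot_ab$missing)
  list(
    f1 = score_counts(tot_ab, scheme)$f1,
    f1_swapped = score_counts(tot_ba, scheme)$f1,
    per_category = per_category
  )
}

# ---- token-level agreement --------------------------------------------------

#' Label every token with the entity annotation covering it
#'
#' A token under two annotations takes the longest one's category (schema
#' order breaks the remaining ties), so each token gets exactly one label.
#' Tokens covered by no entity are labelled `"NONE"`.  Each row carries the
#' line number, category, an attribute fingerprint (sorted feature
#' name=value pairs) and the covering annotation's section.
#'
#' @param text Document text.
#' @param anns Entity annotation table.
#' @param tokens Token table; tokenised from `text` when omitted.
#' @param category_order Tie-break order; defaults to [section_labels()].
#' @return Tibble: `token_id`, `start`, `end`, `line`, `label`,
#'   `fingerprint`, `section`.
#' @export
token_label_table <- function(text, anns, tokens = NULL,
                              category_order = section_labels()) {
  if (is.null(tokens)) tokens <- tokenize(text)
  newlines <- c(0L, which(strsplit(text, "")[[1]] == "\n"))
  line_of <- function(off) sum(newlines <= off)
  ents <- anns[anns$category %in% category_order, , drop = FALSE]
  n <- nrow(tokens)
  label <- rep("NONE", n)
  fingerprint <- rep("", n)
  section <- rep(NA_character_, n)
  for (t in seq_len(n)) {
    cover <- which(ents$start <= tokens$start[t] & tokens$end[t] <= ents$end)
    if (length(cover) == 0) next
    lens <- ents$end[cover] - ents$start[cover]
    ord <- order(-lens, match(ents$category[cover], category_order))
    best <- cover[ord[1]]
    label[t] <- ents$category[best]
    f <- ents$features[[best]]
    f <- f[setdiff(names(f), "section")]
    if (length(f) > 0) {
      nm <- sort(names(f))
      fingerprint[t] <- paste(paste0(nm, "=", vapply(f[nm], norm_feature_value, character(1))),
                              collapse = ";")
    }
    section[t] <- ents$features[[best]]$section %||% NA_character_
  }
  tibble(
    token_id = seq_len(n), start = tokens$start, end = tokens$end,
    line = vapply(tokens$start, line_of, numeric(1)),
    label = label, fingerprint = fingerprint, section = section
  )
}

#' Token-level confusion matrix between two annotators
#'
#' Cell (i, j) counts tokens labelled i by the first annotator and j by the
#' second.  Both tables must be built over the same tokenisation.
#'
#' @param a,b Token label tables from [token_label_table()].
#' @param levels Optional label universe; defaults to the labels observed.
#' @return A square integer matrix with row/column names.
#' @export
token_confusion <- function(a, b, levels = NULL) {
  if (nrow(a) != nrow(b) || !all(a$start == b$start & a$end == b$end)) {
    abort("token universes differ between the two label tables")
  }
  if (is.null(levels)) levels <- sort(unique(c(a$label, b$label, "NONE")))
  tab <- table(factor(a$label, levels = levels), factor(b$label, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(levels, levels))
  m
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' diagonal proportion and chance agreement `p_e` from the marginal products.
#' When `p_e = 1`, kappa is defined as 1 if `p_o = 1`, else 0.
#'
#' @param m Square confusion matrix.
#' @return Kappa value.
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2)) # 0.4
#' @export
cohen_kappa <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- sum(m)
  if (n == 0) abort("confusion matrix total must be positive")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Positive specific agreement for one category
#'
#' `2 * both / (first + second)`: the chance-uncorrected proportion of
#' category markings the two annotators share.  0/0 is defined as 1.
#'
#' @param m Confusion matrix (rows annotator A, columns annotator B).
#' @param category Category name (row/column label).
#' @return Proportion in \[0, 1\].
#' @export
specific_agreement <- function(m, category) {
  if (!category %in% rownames(m)) abort(paste0("category not in matrix: ", category))
  num <- 2 * m[category, category]
  den <- sum(m[category, ]) + sum(m[, category])
  if (den == 0) return(1)
  num / den
}
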