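# Shared fixtures and independent oracles for the test suite.

# memoised shipped resource bundle (loading parses all lexicons and rules)
test_res <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- bcc_resources(system.file("extdata", "bcc", package = "bccner"))
    }
    cache
  }
})

# quick annotation table builder: spans as list of c(start, end), shared
# category, optional feature lists
ann_fix <- function(spans, category = "X", features = NULL) {
  annotation_tbl(
    category = rep(category, length(spans)),
    start = vapply(spans, `[`, numeric(1), 1),
    end = vapply(spans, `[`, numeric(1), 2),
    features = features
  )
}

# Independent feature-compatibility check for the alignment oracle: every
# key feature present in the response with an equal value (string compare
# after lower-casing and whitespace collapse).
oracle_compatible <- function(kf, rf) {
  norm <- function(v) tolower(gsub("[[:space:]]+", " ", trimws(as.character(v))))
  for (nm in setdiff(names(kf), "section")) {
    if (is.null(rf[[nm]])) return(FALSE)
    if (!identical(norm(kf[[nm]]), norm(rf[[nm]]))) return(FALSE)
  }
  TRUE
}

# Exhaustive optimal assignment between key and response annotations:
# maximises (correct, partial) lexicographically over all matchings where a
# pair needs identical category, span overlap and feature compatibility.
# Tractable for a handful of annotations per set.
oracle_align <- function(key, resp) {
  nk <- nrow(key)
  nr <- nrow(resp)
  rel <- matrix(0L, max(nk, 1), max(nr, 1)) # 0 none, 1 partial, 2 correct
  for (i in seq_len(nk)) {
    for (j in seq_len(nr)) {
      if (key$category[i] != resp$category[j]) next
      if (key$start[i] >= resp$end[j] || resp$start[j] >= key$end[i]) next
      if (!oracle_compatible(key$features[[i]], resp$features[[j]])) next
      coext <- key$start[i] == resp$start[j] && key$end[i] == resp$end[j]
      rel[i, j] <- if (coext) 2L else 1L
    }
  }
  best <- c(-1L, -1L)
  recurse <- function(i, used, n_correct, n_partial) {
    if (i > nk) {
      sc <- c(n_correct, n_partial)
      if (sc[1] > best[1] || (sc[1] == best[1] && sc[2] > best[2])) best <<- sc
      return(invisible())
    }
    recurse(i + 1L, used, n_correct, n_partial) # leave key i unmatched
    for (j in seq_len(nr)) {
      if (used[j] || rel[i, j] == 0L) next
      used[j] <- TRUE
      recurse(i + 1L, used,
              n_correct + (rel[i, j] == 2L),
              n_partial + (rel[i, j] == 1L))
      used[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, max(nr, 1)), 0L, 0L)
  list(
    correct = best[1], partial = best[2],
    missing = nk - best[1] - best[2],
    spurious = nr - best[1] - best[2]
  )
}

# random annotation set over a short text: a few annotations, small span
# alphabet so coextensive/overlapping cases are common
random_ann_set <- function(n, text_len = 12, features = TRUE) {
  starts <- sample.int(text_len - 1, n, replace = TRUE) - 1L
  lens <- sample.int(4, n, replace = TRUE)
  ends <- pmin(starts + lens, text_len)
  feats <- if (features) {
    lapply(seq_len(n), function(i) list(v = sample(c("a", "b"), 1)))
  } else {
    NULL
  }
  annotation_tbl(
    category = rep("X", n), start = starts, end = ends, features = feats
  )
}

random_counts <- function() {
  eval_counts(
    correct = sample(0:20, 1), partial = sample(0:20, 1),
    missing = sample(0:20, 1), spurious = sample(0:20, 1)
  )
}
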