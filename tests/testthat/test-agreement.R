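test_that("Cohen's kappa matches closed forms", {
  perfect <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(cohen_kappa(perfect), 1)
  worked <- matrix(c(20, 10, 5, 15), 2) # p_o = 0.7, p_e = 0.5
  expect_equal(cohen_kappa(worked), 0.4, tolerance = 1e-12)
  # degenerate chance agreement: all mass in one cell
  onecell <- matrix(c(5, 0, 0, 0), 2)
  expect_equal(cohen_kappa(onecell), 1)
  skewed <- matrix(c(5, 0, 3, 0), 2) # p_e = 1, p_o < 1
  expect_equal(cohen_kappa(skewed), 0)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "positive")
})

test_that("kappa tends to zero for independent annotators", {
  set.seed(13)
  n <- 20000
  a <- sample(c("X", "NONE"), n, replace = TRUE, prob = c(0.3, 0.7))
  b <- sample(c("X", "NONE"), n, replace = TRUE, prob = c(0.3, 0.7))
  m <- table(factor(a, c("X", "NONE")), factor(b, c("X", "NONE")))
  k <- cohen_kappa(matrix(as.integer(m), 2, dimnames = dimnames(m)))
  expect_lt(abs(k), 3 / sqrt(n) / (1 - 0.58)) # 3 SE of p_o on the kappa scale
})

test_that("token confusion matrices conserve marginals", {
  tx <- "nodular basal cell carcinoma with ulceration"
  toks <- tokenize(tx)
  ann_a <- annotation_tbl("MicroscopicDetails", 0L, 28L)
  ann_b <- annotation_tbl()
  ta <- token_label_table(tx, ann_a, toks)
  tb <- token_label_table(tx, ann_b, toks)
  m <- token_confusion(ta, tb)
  expect_equal(m["MicroscopicDetails", "NONE"], 4) # nodular basal cell carcinoma
  expect_equal(sum(m), nrow(toks))
  expect_equal(
    unname(rowSums(m)),
    as.integer(table(factor(ta$label, levels = rownames(m))))
  )
  # identical tables give a diagonal matrix
  mm <- token_confusion(ta, ta)
  expect_equal(sum(mm) - sum(diag(mm)), 0)
  # differing token universes are an error
  expect_error(token_confusion(ta[-1, ], tb), "universes")
})

test_that("tokens under two annotations take the longest, then schema order", {
  tx <- "deep margin clear"
  anns <- dplyr::bind_rows(
    annotation_tbl("MicroscopicDetails", 0L, 11L, id = 1L),
    annotation_tbl("MicroscopicMeasurements", 0L, 17L, id = 2L)
  )
  tl <- token_label_table(tx, anns)
  expect_equal(unique(tl$label), "MicroscopicMeasurements")
  # equal spans: the schema-earlier category wins
  anns2 <- dplyr::bind_rows(
    annotation_tbl("MicroscopicMeasurements", 0L, 11L, id = 1L),
    annotation_tbl("MicroscopicDetails", 0L, 11L, id = 2L)
  )
  tl2 <- token_label_table(tx, anns2)
  expect_equal(tl2$label[1], "MicroscopicDetails")
})

test_that("specific agreement follows its closed form", {
  perfect <- matrix(c(10, 0, 0, 5), 2, dimnames = list(c("A", "NONE"), c("A", "NONE")))
  expect_equal(specific_agreement(perfect, "A"), 1)
  m <- matrix(c(8, 2, 2, 0), 2, dimnames = list(c("A", "NONE"), c("A", "NONE")))
  expect_equal(specific_agreement(m, "A"), 16 / 20)
  disjoint <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "NONE"), c("A", "NONE")))
  expect_equal(specific_agreement(disjoint, "A"), 0)
  empty <- matrix(c(0, 0, 0, 7), 2, dimnames = list(c("A", "NONE"), c("A", "NONE")))
  expect_equal(specific_agreement(empty, "A"), 1) # 0/0 convention
})

test_that("the full IAA stack runs on simulated annotator pairs", {
  g <- generate_corpus(synth_config(n_reports = 4, seed = 61))
  identical_pair <- generate_annotator_pair(g$gold, g$corpus, rate = 0, seed = 1)
  a <- identical_pair[identical_pair$set == "annotatorA", ]
  b <- identical_pair[identical_pair$set == "annotatorB", ]
  expect_equal(pairwise_f1(a, b)$f1, 1)
  # token-level kappa of identical annotators is 1
  d1 <- g$corpus$doc_id[1]
  tx <- g$corpus$text[1]
  ta <- token_label_table(tx, a[a$doc_id == d1, ])
  tb <- token_label_table(tx, b[b$doc_id == d1, ])
  expect_equal(cohen_kappa(token_confusion(ta, tb)), 1)
  # dropping everything kills specific agreement for affected categories
  dropped <- generate_annotator_pair(g$gold, g$corpus, rate = 1, seed = 2,
                                     perturbation = "drop")
  expect_equal(nrow(dropped), 0)
  tb2 <- token_label_table(tx, dropped[dropped$doc_id == d1 &
                                         dropped$set == "annotatorB", ])
  m <- token_confusion(ta, tb2, levels = sort(unique(c(ta$label, "NONE"))))
  for (cat in setdiff(rownames(m), "NONE")) {
    expect_equal(specific_agreement(m, cat), 0)
  }
})

test_that("mean pairwise F1 does not increase with the disagreement rate", {
  g <- generate_corpus(synth_config(n_reports = 4, seed = 71))
  mean_f1 <- function(rate) {
    f1s <- vapply(1:3, function(s) {
      pair <- generate_annotator_pair(g$gold, g$corpus, rate = rate, seed = s)
      pairwise_f1(
        pair[pair$set == "annotatorA", ],
        pair[pair$set == "annotatorB", ]
      )$f1
    }, numeric(1))
    mean(f1s)
  }
  f <- vapply(c(0, 0.4, 0.9), mean_f1, numeric(1))
  expect_true(all(diff(f) <= 1e-9))
})
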