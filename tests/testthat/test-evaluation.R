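test_that("alignment honours feature inclusion from key into response", {
  key <- ann_fix(list(c(0, 10)), features = list(list(site = "ear")))
  resp <- ann_fix(list(c(0, 10)), features = list(list(site = "ear", extra = "x")))
  cnt <- align_annotations(key, resp)
  expect_equal(cnt$correct, 1)
  expect_equal(cnt$missing + cnt$spurious + cnt$partial, 0)

  # overlap without coextension is partial
  key2 <- ann_fix(list(c(0, 10)))
  resp2 <- ann_fix(list(c(3, 12)))
  cnt2 <- align_annotations(key2, resp2)
  expect_equal(cnt2$partial, 1)
  expect_equal(cnt2$correct, 0)

  # clashing feature values break the pair
  key3 <- ann_fix(list(c(0, 10)), features = list(list(site = "ear")))
  resp3 <- ann_fix(list(c(0, 10)), features = list(list(site = "nose")))
  cnt3 <- align_annotations(key3, resp3)
  expect_equal(cnt3$missing, 1)
  expect_equal(cnt3$spurious, 1)
})

test_that("count identities hold on every alignment output", {
  set.seed(7)
  for (k in 1:50) {
    key <- random_ann_set(sample(0:5, 1) + 1)
    resp <- random_ann_set(sample(0:5, 1) + 1)
    cnt <- align_annotations(key, resp)
    expect_equal(cnt$correct + cnt$partial + cnt$missing, nrow(key))
    expect_equal(cnt$correct + cnt$partial + cnt$spurious, nrow(resp))
  }
})

test_that("published tallies score as expected under each scheme", {
  # clinical details, training corpus: match 49, missing 7, spurious 4, partial 33
  cnt <- eval_counts(correct = 49, partial = 33, missing = 7, spurious = 4)
  lenient <- score_counts(cnt, "lenient")
  expect_equal(lenient$precision, 82 / 86, tolerance = 1e-12)
  expect_equal(lenient$recall, 82 / 89, tolerance = 1e-12)
  avg <- score_counts(cnt, "average")
  expect_equal(avg$precision, 65.5 / 86, tolerance = 1e-12)
  # fixed-format fields, all matches partial: perfect under lenient
  fixed <- eval_counts(correct = 0, partial = 38, missing = 0, spurious = 0)
  sc <- score_counts(fixed, "lenient")
  expect_equal(c(sc$precision, sc$recall, sc$f1), c(1, 1, 1))
  expect_equal(score_counts(fixed, "strict")$f1, 0)
})

test_that("zero denominators follow the empty-vs-empty convention", {
  expect_equal(score_counts(eval_counts(), "lenient")$f1, 1)
  only_missing <- score_counts(eval_counts(missing = 3), "lenient")
  expect_equal(only_missing$precision, 0)
  expect_equal(only_missing$recall, 0)
  only_spurious <- score_counts(eval_counts(spurious = 2), "lenient")
  expect_equal(only_spurious$precision, 0)
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(11)
  for (k in 1:200) {
    sc <- score_counts(random_counts(), sample(c("strict", "average", "lenient"), 1))
    expect_gte(sc$f1 + 1e-12, min(sc$precision, sc$recall))
    expect_lte(sc$f1 - 1e-12, max(sc$precision, sc$recall))
  }
})

make_corpus_anns <- function(doc_scores) {
  # builds per-document gold/system pairs scoring exactly 1 or 0
  rows <- list()
  for (d in seq_along(doc_scores)) {
    id <- paste0("d", d)
    gold <- ann_fix(list(c(0, 5)))
    gold$doc_id <- id
    gold$set <- "gold"
    sys <- if (doc_scores[d] == 1) ann_fix(list(c(0, 5))) else ann_fix(list(c(7, 9)))
    sys$doc_id <- id
    sys$set <- "system"
    rows[[d]] <- dplyr::bind_rows(gold, sys)
  }
  dplyr::bind_rows(rows)
}

test_that("macro equals micro on a single document and averages across docs", {
  one <- evaluate_corpus(make_corpus_anns(1), scheme = "lenient")
  expect_equal(one$macro_overall$f1, one$micro_overall$f1)
  two <- evaluate_corpus(make_corpus_anns(c(1, 0)), scheme = "lenient")
  expect_equal(two$macro_overall$precision, 0.5)
  expect_equal(two$macro_overall$n_docs, 2)
  perfect <- evaluate_corpus(make_corpus_anns(c(1, 1, 1)), scheme = "lenient")
  expect_equal(perfect$macro_overall$precision_lo, 1)
  expect_equal(perfect$macro_overall$precision_hi, 1)
})

test_that("documents lacking one set are listed and skipped", {
  anns <- make_corpus_anns(c(1, 1))
  anns <- anns[!(anns$doc_id == "d2" & anns$set == "system"), ]
  expect_warning(ev <- evaluate_corpus(anns), "d2")
  expect_equal(ev$n_documents, 1)
  expect_equal(ev$skipped, "d2")
})

test_that("tidy and glance expose the evaluation tables", {
  ev <- evaluate_corpus(make_corpus_anns(c(1, 0)))
  td <- tidy(ev)
  expect_true(all(c("category", "precision", "f1_lo") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$n_documents, 2)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("pairwise F1 is 1 on identical sets and 0 on disjoint sets", {
  a <- ann_fix(list(c(0, 5), c(8, 12)))
  expect_equal(pairwise_f1(a, a)$f1, 1)
  b <- ann_fix(list(c(20, 25)))
  expect_equal(pairwise_f1(a, b)$f1, 0)
})

test_that("reference tallies load, score and flag known inconsistencies", {
  tal <- bcc_reference_tallies()
  expect_equal(nrow(tal), 18)
  scored <- score_tallies(tal, "lenient")
  fixed <- scored[scored$entity %in% c("Accession number", "Excision date", "Requestor"), ]
  expect_true(all(fixed$precision == 100))
  expect_true(all(fixed$f1 == 100))
  chk <- tally_identity_check(tal)
  expect_true(any(!chk$response_identity))
})
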