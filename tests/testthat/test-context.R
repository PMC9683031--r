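with_sentences <- function(text, targets) {
  bind_anns <- dplyr::bind_rows(split_sentences(text), targets)
  bind_anns$id <- seq_len(nrow(bind_anns))
  bind_anns
}

trig <- function(term, category, direction = "forward") {
  tibble::tibble(term = term, category = category, direction = direction)
}

polarity <- function(anns, category) {
  rows <- which(anns$category == category)
  list(
    negated = vapply(rows, function(i) isTRUE(anns$features[[i]]$negated), logical(1)),
    affirmed = vapply(rows, function(i) isTRUE(anns$features[[i]]$affirmed), logical(1))
  )
}

test_that("a forward negation trigger negates targets to the sentence end", {
  tx <- "there was no residual disease"
  anns <- with_sentences(tx, annotation_tbl("ResidualDisease", 13L, 29L))
  out <- apply_context(tx, anns, "ResidualDisease", trig("no", "negation"))
  expect_true(polarity(out, "ResidualDisease")$negated)
  expect_false(polarity(out, "ResidualDisease")$affirmed)
})

test_that("an affirmation trigger affirms in-scope targets", {
  tx <- "tumour confined to the dermis"
  anns <- with_sentences(tx, annotation_tbl("Level", 23L, 29L))
  out <- apply_context(tx, anns, "Level",
                       trig("confined to", "affirmation"))
  expect_true(polarity(out, "Level")$affirmed)
  expect_false(polarity(out, "Level")$negated)
})

test_that("scopes never cross a sentence boundary", {
  tx <- "no ulceration. Perineural invasion present."
  targets <- annotation_tbl(
    category = c("Ulceration", "PerineuralInvasion"),
    start = c(3L, 15L), end = c(13L, 34L)
  )
  anns <- with_sentences(tx, targets)
  out <- apply_context(tx, anns, c("Ulceration", "PerineuralInvasion"),
                       trig("no", "negation"))
  expect_true(polarity(out, "Ulceration")$negated)
  expect_false(polarity(out, "PerineuralInvasion")$negated)
})

test_that("termination terms close a scope early", {
  tx <- "no ulceration but perineural invasion present"
  targets <- annotation_tbl(
    category = c("Ulceration", "PerineuralInvasion"),
    start = c(3L, 18L), end = c(13L, 37L)
  )
  anns <- with_sentences(tx, targets)
  triggers <- dplyr::bind_rows(
    trig("no", "negation"),
    trig("but", "termination")
  )
  out <- apply_context(tx, anns, c("Ulceration", "PerineuralInvasion"), triggers)
  expect_true(polarity(out, "Ulceration")$negated)
  expect_false(polarity(out, "PerineuralInvasion")$negated)
})

test_that("pseudo triggers suppress the trigger at their position", {
  tx <- "no increase in the lesion"
  targets <- annotation_tbl("Lesion", 19L, 25L)
  anns <- with_sentences(tx, targets)
  without_pseudo <- apply_context(tx, anns, "Lesion", trig("no", "negation"))
  expect_true(polarity(without_pseudo, "Lesion")$negated)
  with_pseudo <- apply_context(
    tx, anns, "Lesion",
    dplyr::bind_rows(trig("no", "negation"), trig("no increase", "pseudo"))
  )
  expect_false(polarity(with_pseudo, "Lesion")$negated)
})

test_that("backward triggers scope from the sentence start", {
  tx <- "perineural invasion not identified"
  targets <- annotation_tbl("PerineuralInvasion", 0L, 19L)
  anns <- with_sentences(tx, targets)
  out <- apply_context(tx, anns, "PerineuralInvasion",
                       trig("not identified", "negation", "backward"))
  expect_true(polarity(out, "PerineuralInvasion")$negated)
})

test_that("without triggers every polarity stays unset", {
  tx <- "there was no residual disease"
  anns <- with_sentences(tx, annotation_tbl("ResidualDisease", 13L, 29L))
  out <- apply_context(tx, anns, "ResidualDisease",
                       tibble::tibble(term = character(), category = character(),
                                      direction = character()))
  expect_false(polarity(out, "ResidualDisease")$negated)
  expect_false(polarity(out, "ResidualDisease")$affirmed)
})

test_that("negation takes precedence so both polarities are never set", {
  tx <- "no tumour confined to the dermis"
  anns <- with_sentences(tx, annotation_tbl("Level", 26L, 32L))
  out <- apply_context(
    tx, anns, "Level",
    dplyr::bind_rows(trig("no", "negation"), trig("confined to", "affirmation"))
  )
  pol <- polarity(out, "Level")
  expect_true(pol$negated)
  expect_false(pol$affirmed)
})

test_that("an optional token window caps forward scopes", {
  tx <- "no evidence of residual tumour at the deep aspect margin region"
  targets <- annotation_tbl("Margin", 51L, 57L) # "margin"
  anns <- with_sentences(tx, targets)
  unlimited <- apply_context(tx, anns, "Margin", trig("no", "negation"))
  expect_true(polarity(unlimited, "Margin")$negated)
  capped <- apply_context(tx, anns, "Margin", trig("no", "negation"),
                          window_tokens = 3)
  expect_false(polarity(capped, "Margin")$negated)
})

test_that("trigger matching shares gazetteer longest-match semantics", {
  # multi-word trigger wins over its single-word prefix at the same offset
  tx <- "margins clear of tumour"
  targets <- annotation_tbl("Tumour", 17L, 23L)
  anns <- with_sentences(tx, targets)
  out <- apply_context(
    tx, anns, "Tumour",
    dplyr::bind_rows(trig("clear", "negation"), trig("clear of", "affirmation"))
  )
  pol <- polarity(out, "Tumour")
  expect_true(pol$affirmed)
  expect_false(pol$negated)
})
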