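write_phase <- function(yaml_text) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
  writeLines(yaml_text, path)
  path
}

lookup_anns <- function(...) {
  specs <- list(...)
  annotation_tbl(
    category = vapply(specs, `[[`, character(1), "cat"),
    start = vapply(specs, `[[`, numeric(1), "start"),
    end = vapply(specs, `[[`, numeric(1), "end"),
    features = lapply(specs, function(s) s$f %||% list())
  )
}
`%||%` <- rlang::`%||%`

two_lookup_phase <- function(control = "appelt") {
  read_rule_phase(write_phase(sprintf("
phase: {name: p, control: %s, input: [Lookup]}
rules:
  - name: SubDiag
    priority: 10
    pattern:
      - {category: Lookup, features: {majorType: subtype}, bind: sub}
      - {category: Lookup, features: {majorType: diagnosis}}
    actions:
      - create:
          category: MicroscopicDetails
          span: match
          features: {subtype: {from: sub}}
", control)))
}

test_that("a sequence rule fires on adjacent lookups and copies bindings", {
  tx <- "nodular basal cell carcinoma"
  anns <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 7, f = list(majorType = "subtype")),
    list(cat = "Lookup", start = 8, end = 28, f = list(majorType = "diagnosis"))
  )
  out <- run_phase(two_lookup_phase(), tx, anns)
  md <- ann_select(out, "MicroscopicDetails")
  expect_equal(nrow(md), 1)
  expect_equal(c(md$start, md$end), c(0L, 28L))
  expect_equal(md$features[[1]]$subtype, "nodular")
  # no subtype, no match
  alone <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 20, f = list(majorType = "diagnosis"))
  )
  out2 <- run_phase(two_lookup_phase(), "basal cell carcinoma", alone)
  expect_equal(nrow(ann_select(out2, "MicroscopicDetails")), 0)
})

test_that("appelt control picks longest, then priority, then file order", {
  phase <- read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: Short
    priority: 99
    pattern:
      - {category: Lookup, features: {k: a}}
    actions:
      - create: {category: Out, span: match, features: {by: short}}
  - name: Long
    priority: 1
    pattern:
      - {category: Lookup, features: {k: a}}
      - {category: Lookup, features: {k: b}}
    actions:
      - create: {category: Out, span: match, features: {by: long}}
"))
  anns <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 3, f = list(k = "a")),
    list(cat = "Lookup", start = 4, end = 8, f = list(k = "b"))
  )
  out <- run_phase(phase, "abc defg", anns)
  expect_equal(ann_feature(ann_select(out, "Out"), "by"), "long")

  # equal length: priority decides
  phase2 <- read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: LowPrio
    priority: 5
    pattern: [{category: Lookup, features: {k: a}}]
    actions: [{create: {category: Out, span: match, features: {by: low}}}]
  - name: HighPrio
    priority: 10
    pattern: [{category: Lookup, features: {k: a}}]
    actions: [{create: {category: Out, span: match, features: {by: high}}}]
"))
  one <- lookup_anns(list(cat = "Lookup", start = 0, end = 3, f = list(k = "a")))
  out2 <- run_phase(phase2, "abc", one)
  expect_equal(ann_feature(ann_select(out2, "Out"), "by"), "high")

  # equal length and priority: declaration order decides
  phase3 <- read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: First
    priority: 5
    pattern: [{category: Lookup, features: {k: a}}]
    actions: [{create: {category: Out, span: match, features: {by: first}}}]
  - name: Second
    priority: 5
    pattern: [{category: Lookup, features: {k: a}}]
    actions: [{create: {category: Out, span: match, features: {by: second}}}]
"))
  out3 <- run_phase(phase3, "abc", one)
  expect_equal(ann_feature(ann_select(out3, "Out"), "by"), "first")
})

test_that("remove actions delete bound annotations", {
  phase <- read_rule_phase(write_phase("
phase: {name: cleanup, control: all, input: [Lookup]}
rules:
  - name: Drop
    priority: 0
    pattern: [{category: Lookup, bind: l}]
    actions: [{remove: l}]
"))
  anns <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 3),
    list(cat = "Lookup", start = 5, end = 9),
    list(cat = "Keep", start = 0, end = 2)
  )
  out <- run_phase(phase, "abc defgh", anns)
  expect_equal(nrow(ann_select(out, "Lookup")), 0)
  expect_equal(nrow(ann_select(out, "Keep")), 1)
})

test_that("malformed rules are rejected at load time with diagnostics", {
  expect_error(
    read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: Bad
    pattern: [{category: Lookup}]
    actions: [{create: {category: Out, span: nosuch}}]
")),
    "unbound label 'nosuch'"
  )
  expect_error(
    read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: BadQ
    pattern: [{category: Lookup, quantifier: {min: 3, max: 1}}]
    actions: [{create: {category: Out, span: match}}]
")),
    "quantifier"
  )
  expect_error(
    read_rule_phase(write_phase("
phase: {name: p, control: wild, input: [Lookup]}
rules: []
")),
    "control"
  )
  expect_error(
    read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: Dup
    pattern: [{category: Lookup}]
    actions: [{create: {category: Out, span: match}}]
  - name: Dup
    pattern: [{category: Lookup}]
    actions: [{create: {category: Out, span: match}}]
")),
    "duplicate rule names"
  )
})

test_that("a cascade with a forward dependency is rejected", {
  p1 <- write_phase("
phase: {name: early, control: appelt, input: [Later]}
rules:
  - name: R
    pattern: [{category: Later}]
    actions: [{create: {category: Out, span: match}}]
")
  p2 <- write_phase("
phase: {name: late, control: appelt, input: [Lookup]}
rules:
  - name: Mk
    pattern: [{category: Lookup}]
    actions: [{create: {category: Later, span: match}}]
")
  expect_error(read_cascade(c(p1, p2)), "cascade ordering")
  # reversed order is fine
  expect_length(read_cascade(c(p2, p1)), 2)
})

test_that("cascades are deterministic, identity on empty phase lists, and
           independent phases commute", {
  tx <- "nodular basal cell carcinoma"
  anns <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 7, f = list(majorType = "subtype")),
    list(cat = "Lookup", start = 8, end = 28, f = list(majorType = "diagnosis"))
  )
  expect_identical(run_cascade(list(), tx, anns), anns)
  pA <- read_rule_phase(write_phase("
phase: {name: a, control: all, input: [Lookup]}
rules:
  - name: MkA
    pattern: [{category: Lookup, features: {majorType: subtype}}]
    actions: [{create: {category: OutA, span: match}}]
"))
  pB <- read_rule_phase(write_phase("
phase: {name: b, control: all, input: [Lookup]}
rules:
  - name: MkB
    pattern: [{category: Lookup, features: {majorType: diagnosis}}]
    actions: [{create: {category: OutB, span: match}}]
"))
  ab <- run_cascade(list(pA, pB), tx, anns)
  ba <- run_cascade(list(pB, pA), tx, anns)
  strip_ids <- function(x) x[order(x$category, x$start), c("category", "start", "end")]
  expect_equal(strip_ids(ab), strip_ids(ba))
  expect_identical(run_cascade(list(pA, pB), tx, anns),
                   run_cascade(list(pA, pB), tx, anns))
})

test_that("appelt phases never create overlapping annotations of one rule", {
  res <- test_res()
  g <- generate_corpus(synth_config(n_reports = 3, seed = 21))
  for (i in seq_len(nrow(g$corpus))) {
    anns <- bcc_annotate(g$corpus$text[i], res)
    meas <- ann_select(anns, "MicroscopicMeasurements")
    if (nrow(meas) > 1) {
      for (a in seq_len(nrow(meas) - 1)) {
        expect_true(meas$start[a + 1] >= meas$end[a])
      }
    }
  }
})

test_that("quantified elements match greedily with backtracking", {
  phase <- read_rule_phase(write_phase("
phase: {name: p, control: appelt, input: [Lookup]}
rules:
  - name: Star
    pattern:
      - {category: Lookup, features: {k: a}, quantifier: plus, bind: run}
      - {category: Lookup, features: {k: z}}
    actions:
      - create: {category: Out, span: run}
"))
  anns <- lookup_anns(
    list(cat = "Lookup", start = 0, end = 2, f = list(k = "a")),
    list(cat = "Lookup", start = 3, end = 5, f = list(k = "a")),
    list(cat = "Lookup", start = 6, end = 8, f = list(k = "z"))
  )
  out <- run_phase(phase, "aa aa zz", anns)
  o <- ann_select(out, "Out")
  expect_equal(nrow(o), 1)
  expect_equal(c(o$start, o$end), c(0L, 5L)) # span of the bound plus-run
})
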