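test_that("the built-in prognostic factor filter parses to the expected AST", {
  pf <- builtin_strategies()$pf_filter
  expect_length(pf$lines, 14)
  final <- pf$lines[[14]]
  expect_equal(final$type, "combo")
  expect_equal(final$op, "or")
  expect_equal(final$refs, 1:13)
  tw <- Filter(function(nd) nd$type == "textword", pf$lines)
  expect_setequal(vapply(tw, `[[`, "", "term"),
                  c("risk", "cohort", "prognos", "predict", "incidence",
                    "survival", "causal factor", "course"))
  trunc <- vapply(tw, function(nd) nd$truncated, logical(1))
  expect_setequal(vapply(tw[trunc], `[[`, "", "term"), c("prognos", "predict"))
  exp_mesh <- Filter(function(nd) nd$type == "mesh" && nd$explode, pf$lines)
  expect_setequal(vapply(exp_mesh, `[[`, "", "heading"),
                  c("Risk", "Cohort Studies", "Prognosis", "Incidence",
                    "Survival Analysis"))
})

test_that("the Haynes broad filter has six leaves and serializes round-trip", {
  b <- builtin_strategies()
  leaves <- Filter(function(nd) nd$type != "combo", b$haynes_broad$lines)
  expect_length(leaves, 6)
  for (s in b) {
    again <- parse_strategy(paste(format_strategy(s), collapse = "\n"),
                            name = s$name)
    expect_equal(again$lines, s$lines)
  }
})

test_that("parser accepts simple leaves and rejects bad references/suffixes", {
  s <- parse_strategy("1 risk.tw")
  expect_equal(s$lines[[1]],
               list(type = "textword", term = "risk", truncated = FALSE,
                    fields = c("title", "abstract")))
  expect_error(parse_strategy("1 risk.tw\n2 or/1-5"), "line 2")
  expect_error(parse_strategy("1 risk.mp"), "suffix")
  expect_error(parse_strategy("1 risk.tw\n3 cohort.tw"), "consecutive")
  # en-dash ranges normalize
  s2 <- parse_strategy("1 risk.tw\n2 cohort.tw\n3 or/1–2")
  expect_equal(s2$lines[[3]]$refs, 1:2)
})

test_that("textword matching: truncation, case, adjacency, tokenization", {
  prognos <- parse_strategy('1 "prognos*".tw')$lines[[1]]
  r <- bib_records("1", "Prognostic significance of X")
  expect_true(evaluate_line(prognos, r))
  expect_false(evaluate_line(prognos, bib_records("2", "No progression here")))

  cf <- parse_strategy('1 "causal factor".tw')$lines[[1]]
  adj <- bib_records("1", "T", "thought to be a causal factor in disease")
  nonadj <- bib_records("2", "T", "a causal risk factor in disease")
  expect_true(evaluate_line(cf, adj))
  expect_false(evaluate_line(cf, nonadj))

  # token split on punctuation lets hyphenated compounds match
  surv <- parse_strategy("1 survival.tw")$lines[[1]]
  expect_true(evaluate_line(surv, bib_records("1", "Disease-free-survival")))
  # whole-token: no infix matching without truncation
  risk <- parse_strategy("1 risk.tw")$lines[[1]]
  expect_false(evaluate_line(risk, bib_records("1", "Asterisked riskier")))
})

test_that("MeSH explosion follows the tree; noexp is exact", {
  tr <- toy_mesh_tree()
  r <- bib_records("1", "T", mesh = list("Risk Factors"))
  expect_true(evaluate_line(parse_strategy("1 exp Risk/")$lines[[1]], r, tr))
  expect_false(evaluate_line(parse_strategy("1 Risk/")$lines[[1]], r, tr))
  # heading comparison is case- and punctuation-insensitive
  r2 <- bib_records("2", "T", mesh = list("follow-up studies"))
  noexp <- parse_strategy("1 Follow-Up Studies/")$lines[[1]]
  expect_true(evaluate_line(noexp, r2, tr))
})

test_that("apply_strategy retrieves the expected toy records", {
  res <- apply_strategy(builtin_strategies()$pf_filter, toy_corpus(),
                        toy_mesh_tree())
  expect_setequal(as.character(res), c("1", "2", "3"))
  # per-line sets are exposed
  lm <- attr(res, "line_matches")
  expect_length(lm, 14)
  expect_equal(lm[[8]], "2")   # exp Incidence/
  # empty corpus and single-leaf identity
  expect_length(apply_strategy("1 risk.tw", toy_corpus()[0, ]), 0)
  one <- apply_strategy("1 survival.tw", toy_corpus())
  expect_equal(as.character(one), "1")
})

test_that("an empty tree degrades explosion to exact match with a warning", {
  r <- bib_records("1", "T", mesh = list("Risk Factors"))
  expect_warning(res <- apply_strategy("1 exp Risk/", r, NULL), "MeSH tree")
  expect_length(res, 0)
})

test_that("apply_strategy agrees with a naive per-record oracle", {
  tr <- toy_mesh_tree()
  strategies <- c(builtin_strategies(),
                  list(mixed = parse_strategy(paste(
                    "1 risk.tw", "2 exp Cohort Studies/", "3 1 and 2",
                    "4 \"prognos*\".tw", "5 3 or 4", "6 5 not 1",
                    sep = "\n"))))
  for (seed in c(3, 17)) {
    corpus <- generate_corpus(corpus_spec(n_relevant = 30, n_irrelevant = 120,
                                          mean_abstract_length = 25,
                                          seed = seed))$records
    for (s in strategies) {
      expect_setequal(as.character(apply_strategy(s, corpus, tr)),
                      oracle_apply(s, corpus, tr))
    }
  }
})

test_that("adding an OR disjunct never shrinks the retrieved set", {
  tr <- toy_mesh_tree()
  corpus <- generate_corpus(corpus_spec(n_relevant = 40, n_irrelevant = 80,
                                        mean_abstract_length = 25,
                                        seed = 5))$records
  base <- parse_strategy("1 risk.tw\n2 cohort.tw\n3 or/1-2")
  wider <- parse_strategy("1 risk.tw\n2 cohort.tw\n3 survival.tw\n4 or/1-3")
  expect_true(all(apply_strategy(base, corpus, tr) %in%
                  apply_strategy(wider, corpus, tr)))
})

test_that("the filter's final line equals the union of its leaf lines", {
  tr <- toy_mesh_tree()
  corpus <- generate_corpus(corpus_spec(n_relevant = 50, n_irrelevant = 100,
                                        mean_abstract_length = 30,
                                        seed = 9))$records
  res <- apply_strategy(builtin_strategies()$pf_filter, corpus, tr)
  lm <- attr(res, "line_matches")
  expect_setequal(as.character(res),
                  unique(unlist(lm[1:13], use.names = FALSE)))
})

test_that("an exploded heading always retrieves a superset of noexp", {
  tr <- toy_mesh_tree()
  corpus <- generate_corpus(corpus_spec(n_relevant = 40, n_irrelevant = 60,
                                        seed = 21))$records
  for (h in c("Risk", "Cohort Studies", "Prognosis", "Survival Analysis")) {
    with_exp <- apply_strategy(paste0("1 exp ", h, "/"), corpus, tr)
    without <- apply_strategy(paste0("1 ", h, "/"), corpus, tr)
    expect_true(all(without %in% with_exp))
  }
})

test_that("strategy JSON serialization carries the full AST", {
  js <- jsonlite::fromJSON(strategy_to_json(builtin_strategies()$pf_filter),
                           simplifyVector = FALSE)
  expect_equal(js$name, "pf_filter")
  expect_length(js$lines, 14)
  expect_equal(js$lines[[14]]$op, "or")
})
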