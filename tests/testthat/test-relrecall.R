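test_that("build_confusion performs the Table-style set arithmetic", {
  ct <- build_confusion(as.character(1:10), c("1", "2", "3"),
                        reference_set("toy", c("1", "4")))
  expect_equal(unclass(ct)[c("a", "b", "c", "d")],
               list(a = 1L, b = 2L, c = 1L, d = 6L))
  # filter == baseline: d = 0
  full <- build_confusion(as.character(1:5), as.character(1:5),
                          reference_set("toy", c("2", "3")))
  expect_equal(full$d, 0L)
  # empty filter: a = b = 0
  none <- build_confusion(as.character(1:5), character(0),
                          reference_set("toy", "2"))
  expect_equal(c(none$a, none$b), c(0L, 0L))
})

test_that("build_confusion rejects ids that break the relative-recall premise", {
  expect_error(
    build_confusion(as.character(1:5), "9", reference_set("toy", "1")),
    "9")
  expect_error(
    build_confusion(as.character(1:5), "1", reference_set("toy", c("1", "77"))),
    "77")
})

test_that("compute_metrics evaluates the five formulas exactly", {
  m <- compute_metrics(confusion_table(7, 80, 0, 13))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100 * 13 / 93)
  expect_equal(m$precision, 100 * 7 / 87)
  expect_equal(m$nnr, 87 / 7)
  expect_equal(m$time_saved, 13)
  d <- display_metrics(m)
  expect_equal(unlist(d), c(sensitivity = 100, specificity = 14, precision = 8,
                            nnr = 12, time_saved = 13))

  perfect <- compute_metrics(confusion_table(1, 0, 0, 1))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "precision",
                                "nnr", "time_saved")]),
               c(sensitivity = 100, specificity = 100, precision = 100,
                 nnr = 1, time_saved = 50))

  kamiya <- compute_metrics(confusion_table(12, 58, 0, 50))
  expect_equal(kamiya$precision, 100 * 12 / 70)
  expect_equal(round(kamiya$precision, 2), 17.14)
  expect_equal(round(kamiya$nnr, 2), 5.83)
  expect_equal(round(kamiya$time_saved, 2), 41.67)

  expect_error(compute_metrics(confusion_table(0, 3, 0, 4)), "reference")
  empty_filter <- compute_metrics(confusion_table(0, 0, 2, 8))
  expect_false(empty_filter$precision_defined)
  expect_true(is.nan(empty_filter$precision))
  expect_true(is.nan(empty_filter$nnr))
})

test_that("back_derive_counts reconstructs published 2x2 cells", {
  pinheiro <- back_derive_counts(3, 1314, 100, 37)
  expect_equal(unclass(pinheiro)[c("a", "b", "c", "d")],
               list(a = 3L, b = 826L, c = 0L, d = 485L))
  westby <- back_derive_counts(16, 784, 31.25, 70)
  expect_equal(unclass(westby)[c("a", "b", "c", "d")],
               list(a = 5L, b = 230L, c = 11L, d = 538L))
  takagi <- back_derive_counts(7, 100, 100, 14)
  expect_equal(unclass(takagi)[c("a", "b", "c", "d")],
               list(a = 7L, b = 80L, c = 0L, d = 13L))
  # forward check: the counts regenerate the printed Pinheiro metrics
  m <- compute_metrics(pinheiro)
  d <- display_metrics(m, precision_digits = 1)
  expect_equal(c(d$sensitivity, d$specificity, d$precision, d$time_saved),
               c(100, 37, 0.4, 37))
  expect_error(back_derive_counts(0, 10, 50, 50))
})

test_that("cell counts are conserved for every evaluation", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    baseline <- as.character(seq_len(n))
    filt <- sample(baseline, sample.int(n, 1))
    ref <- sample(baseline, sample.int(min(n, 30), 1))
    ct <- build_confusion(baseline, filt, reference_set("r", ref))
    expect_equal(ct$a + ct$b + ct$c + ct$d, n)
  }
})

test_that("enlarging the retrieved set moves the metrics monotonically", {
  set.seed(32)
  baseline <- as.character(1:150)
  ref <- reference_set("r", sample(baseline, 25))
  small <- sample(baseline, 40)
  large <- union(small, sample(baseline, 50))
  m_small <- compute_metrics(build_confusion(baseline, small, ref))
  m_large <- compute_metrics(build_confusion(baseline, large, ref))
  expect_gte(m_large$sensitivity, m_small$sensitivity)
  expect_lte(m_large$specificity, m_small$specificity)
  expect_lte(m_large$time_saved, m_small$time_saved)
  # retrieving everything: the boundary case
  m_all <- compute_metrics(build_confusion(baseline, baseline, ref))
  expect_equal(c(m_all$sensitivity, m_all$specificity, m_all$time_saved),
               c(100, 0, 0))
})

test_that("evaluate_review composes the query engine with the metrics", {
  # every reference record carries a prognosis word: sensitivity 100
  rel <- bib_records(paste0("r", 1:6),
                     paste("Prognostic value of marker", 1:6))
  irr <- bib_records(paste0("x", 1:10), paste("Unrelated title", 1:10))
  corpus <- dplyr::bind_rows(rel, irr)
  res <- evaluate_review(corpus, builtin_strategies()$pf_filter,
                         toy_mesh_tree(), reference_set("demo", rel$id))
  expect_equal(res$metrics$sensitivity, 100)
  expect_equal(res$confusion$a + res$confusion$b + res$confusion$c +
                 res$confusion$d, nrow(corpus))
  # a strategy matching nothing: sensitivity 0, time saved 100
  nothing <- evaluate_review(corpus, "1 zzzznonexistent.tw", toy_mesh_tree(),
                             reference_set("demo", rel$id))
  expect_equal(nothing$metrics$sensitivity, 0)
  expect_equal(nothing$metrics$time_saved, 100)
})

test_that("metrics on a planted-probability corpus match closed-form expectations", {
  terms <- data.frame(term = c("prognostic", "cohort"),
                      p_relevant = c(0.7, 0.4), p_irrelevant = c(0.1, 0.05))
  spec <- corpus_spec(n_relevant = 300, n_irrelevant = 700,
                      signal_terms = terms,
                      mesh_signal = data.frame(heading = character(),
                                               p_relevant = numeric(),
                                               p_irrelevant = numeric()),
                      mean_abstract_length = 25, seed = 77)
  corpus <- generate_corpus(spec)
  strat <- parse_strategy("1 prognostic.tw\n2 cohort.tw\n3 or/1-2")
  res <- evaluate_review(corpus$records, strat, NULL, corpus$reference)
  exp_sens <- expected_retrieval_pct(terms$p_relevant)      # 82%
  exp_spec <- 100 - expected_retrieval_pct(terms$p_irrelevant) # 85.5%
  # 4-sigma binomial tolerance at the planted sizes
  tol_sens <- 400 * sqrt(exp_sens / 100 * (1 - exp_sens / 100) / 300)
  tol_spec <- 400 * sqrt(exp_spec / 100 * (1 - exp_spec / 100) / 700)
  expect_lt(abs(res$metrics$sensitivity - exp_sens), tol_sens)
  expect_lt(abs(res$metrics$specificity - exp_spec), tol_spec)
})
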