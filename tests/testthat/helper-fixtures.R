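# Shared fixtures and independent oracles for the test suite.

# Naive per-record strategy evaluation, independent of apply_strategy's
# vectorized per-line machinery: walks the AST for one record at a time.
oracle_apply <- function(strategy, records, tree = NULL) {
  hit <- vapply(seq_len(nrow(records)), function(i) {
    res <- logical(length(strategy$lines))
    for (j in seq_along(strategy$lines)) {
      nd <- strategy$lines[[j]]
      res[j] <- if (nd$type == "combo") {
        vals <- res[nd$refs]
        switch(nd$op,
               or = any(vals),
               and = all(vals),
               not = vals[1] && !any(vals[-1]))
      } else {
        evaluate_line(nd, records[i, ], tree)
      }
    }
    res[length(res)]
  }, logical(1))
  records$id[hit]
}

# Closed-form Pearson chi-square for a 2x2 presence/absence table,
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)); Yates subtracts N/2 from |ad - bc|.
oracle_chi2 <- function(pos_with, pos_total, neg_with, neg_total,
                        yates = FALSE) {
  a <- pos_with; b <- pos_total - pos_with
  c <- neg_with; d <- neg_total - neg_with
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Small deterministic corpus used across query-engine tests: one record
# per retrieval route plus one matching nothing.
toy_corpus <- function() {
  bib_records(
    id = c("1", "2", "3", "4"),
    title = c("Survival of patients with sepsis",
              "An observational study",
              "Biomarkers in early disease",
              "A trial of treatment X"),
    abstract = c("",
                 "",
                 "The model predicted outcome at one year.",
                 "No relevant methodological language here."),
    mesh = list(character(), "Incidence", character(), "Humans")
  )
}

medline_entry <- function(pmid, ti, ab = NULL, mh = character(), dp = NULL) {
  c(paste0("PMID- ", pmid),
    paste0("TI  - ", ti),
    if (!is.null(ab)) paste0("AB  - ", ab),
    if (length(mh)) paste0("MH  - ", mh),
    if (!is.null(dp)) paste0("DP  - ", dp),
    "")
}
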