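# filterlab

Tools for developing and evaluating **methodological search filters** for
bibliographic databases, built around the prognostic factor (PF) filter for
Ovid MEDLINE.

Systematic reviewers use search filters — fixed OR-combinations of MeSH
headings and free-text terms ANDed onto a topic search — to cut the number
of records screened. Developing one involves: assembling a reference set of
known-relevant studies (*relative recall*: the studies included in existing
systematic reviews whose searches can be replicated), selecting candidate
terms by word-frequency and chi-square analysis of the included versus
excluded records, filtering the candidates through an expert Delphi panel
under RAND/UCLA appropriateness rules, and finally scoring the filter
against each review's baseline search. `filterlab` implements that whole
workflow offline, for information specialists and methods researchers who
want to build, audit or re-evaluate filters against local corpora.

## What it computes

Scoring a filter against one review cross-classifies the baseline search
result *N* into the Table-style 2×2 (A retrieved & relevant, B retrieved &
not relevant, C missed relevant, D excluded non-relevant) and reports

| measure | formula |
|---|---|
| sensitivity | A/(A+C) × 100 |
| specificity | D/(B+D) × 100 |
| precision (PPV) | A/(A+B) × 100 |
| number needed to read (NNR) | (1/precision) × 100 |
| time saved | (C+D)/N × 100 |

Per-review sensitivities and specificities are pooled across reviews by
random-effects meta-analysis of proportions: Freeman–Tukey double-arcsine
transform `t = asin√(e/(n+1)) + asin√((e+1)/(n+1))` with variance
`1/(n+0.5)`, DerSimonian–Laird τ², and Miller's harmonic-mean
back-transform (a logit route is also provided). Candidate-term selection
uses document-frequency analysis of titles/abstracts with per-term 2×2
chi-square tests, and Delphi ratings are classified by the median-tertile
rule (appropriate = median 7–9 without panel disagreement).

The package ships two executable strategies: `pf_filter`, the 14-line
prognostic factor filter (5 exploded MeSH headings + 8 textword terms,
with `prognos*`/`predict*` truncated), and `haynes_broad`, the Haynes
broad prognosis filter. The query engine interprets the Ovid dialect they
are written in — `exp Heading/` explosion over a MeSH tree, `.tw` textword
search with whole-token matching, adjacency for multi-word terms, and
trailing truncation.

## Worked example

Evaluate the built-in PF filter on the bundled synthetic demo corpus
(50 records, 12 of them reference-set members):

```r
library(filterlab)
baseline <- read_records(system.file("extdata", "demo_baseline.medline",
                                     package = "filterlab"))
ref <- read_reference_set(system.file("extdata", "demo_reference.txt",
                                      package = "filterlab"), label = "demo")
res <- evaluate_review(baseline, builtin_strategies()$pf_filter,
                       toy_mesh_tree(), ref)
res$metrics
#>    a  b c d sensitivity specificity precision nnr time_saved
#> 1 12 30 0 8         100       21.05     28.57 3.5         16
```

All 12 planted relevant records are retrieved (sensitivity 100%), 8 of the
38 irrelevant ones are excluded (specificity 21%), and a screener reads
3.5 records per relevant record found.

Pooling the six published per-review evaluations (2×2 cells reconstructed
from the printed summary rows with `back_derive_counts()`):

```r
pe <- published_evaluations("pf")
pool_proportions(data.frame(label = pe$review, events = pe$a,
                            total = pe$included_n))
#> <pooled_estimate> ft_dl, k = 6: 95.3% (95% CI 68.5-100.0), tau2 = 0.5098
```

i.e. an overall filter sensitivity of 95%.

A command-line wrapper covering the same operations (`apply`, `evaluate`,
`backderive`, `discover`, `delphi`, `pool`, `synth`) is installed at
`system.file("exec", "filterlab", package = "filterlab")`.

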