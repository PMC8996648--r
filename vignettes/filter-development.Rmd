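---
title: "Developing and evaluating search filters with filterlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating search filters with filterlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filterlab)
```

## The problem

A methodological search filter is an OR-combination of MeSH headings and
free-text terms that, ANDed onto a topic search, restricts the result to a
study type — here, prognostic factor (PF) studies, which are poorly indexed
and heterogeneous in design, so that no single heading retrieves them. The
package implements the full development-and-evaluation cycle: reference-set
assembly by relative recall, candidate-term discovery, expert-panel
selection, Boolean execution, per-review scoring, and cross-review pooling.

Relative recall sidesteps hand-built gold standards: the studies *included*
in existing systematic reviews form the reference set, and each review's
own (replicable) baseline search defines the universe of records the
filter is judged in. The premise is that every reference record is present
in its baseline result; `build_confusion()` enforces this and refuses to
score an evaluation in which it fails, listing the offending ids.

## Query-engine semantics

The engine interprets the Ovid dialect the filters are written in, with
deliberately explicit semantics:

* **Tokenization.** Text is lowercased and split on runs of
  non-alphanumeric characters; there is no stemming, and trailing `*`
  truncation (token-prefix match on the final word) is the only wildcard.
  This reproduces `prognos*`-style matching without hidden normalization.
  A side effect worth knowing: hyphenated compounds split into tokens, so
  `survival.tw` matches "disease-free-survival". Whether the original
  Ovid runs behaved identically is unknowable from the outside; the rule
  is documented rather than claimed.
* **Fields.** `.tw` is interpreted as title + abstract. Real Ovid `.tw`
  spans further fields, but title and abstract are the only text fields in
  scope here, and records lacking an abstract simply match on the title.
* **Multi-word terms** (`"causal factor".tw`) must occur as adjacent
  tokens within one field; "causal risk factor" does not match.
* **Explosion.** `exp Heading/` matches the heading or any descendant in
  the supplied MeSH tree, where descent is exactly tree-number prefix
  extension. Heading comparison ignores case and punctuation ("follow up
  studies" equals "Follow-Up Studies"). With no tree, explosion degrades
  to exact match with a single warning. The bundled `toy_mesh_tree()` is
  a small synthetic hierarchy (~20 headings, invented tree numbers
  mimicking MeSH style) sufficient to exercise every exploded heading the
  built-in strategies use; the full MeSH vocabulary is not shipped.
* **Line combos.** `or/1-13` (en-dash accepted and normalized, since
  published strategies often typeset ranges that way), `1 and 2`, and
  `A not B` = A minus the union of the rest. References must point to
  earlier lines; numbering must be consecutive from 1.

The PubMed-syntax Haynes broad filter is shipped pre-translated
(`[MeSH:noexp]` → plain heading, `[MeSH Terms]` → exploded, `[Text Word]`
→ `.tw`) rather than parsed: it serves only as a fixed comparator, so a
PubMed grammar would be dead weight.

## Candidate-term statistics

`word_frequency()` counts lowercased tokens of title + abstract, excluding
stopwords from unigrams and forming bigrams only from adjacent
non-stopword token pairs. The frequency analysis feeding a filter was
historically run in external tools with unpublished stopword lists, so the
bundled list (`default_stopwords()`, ~130 function words) is an explicit,
replaceable choice.

`term_chi_square()` tests *document* presence/absence (not occurrence
counts) in the positive versus negative set — the contingency unit is the
study — via `stats::chisq.test()`, optionally with Yates correction; both
counts are still reported so occurrence-based analyses remain possible.
Degenerate tables (term in no or in every record overall) return
chi² = 0, p = 1 rather than erroring, since they carry no discriminating
information. `rank_candidate_terms()` orders by positive-set document
frequency (ties: chi² descending, then lexicographic); screening for
*methodological* as opposed to clinical-content terms is left to the human
panel stage, exactly because that screening is judgment, not counting. At
realistic reference-set sizes (tens of positives) even well-planted terms
rarely reach p < 0.05 — which is why frequency analysis is complemented by
a panel rather than a significance cutoff.

## Delphi aggregation

Ratings are 1–9 appropriateness scores. `classify_term()` uses the
median-tertile rule: median 7–9 appropriate, 1–3 inappropriate, otherwise
uncertain; even-panel medians are the mean of the middle two, and
half-integer medians falling between tertiles (3.5, 6.5) are classified
uncertain — the conservative reading. Disagreement requires at least
`ceiling(n/3)` ratings in 1–3 *and* in 7–9 simultaneously, and overrides
any category to uncertain. The one-third extreme fraction is the classic
appropriateness-method convention for panels larger than nine; it is a
parameter (`extreme_fraction`) because published filter projects rarely
state the exact variant used. Only the final round determines selection:
earlier rounds are feedback rounds, and the table may legitimately contain
them with different term coverage.

## Scoring and back-derivation

`compute_metrics()` evaluates the five standard formulas exactly and never
rounds; `display_metrics()` applies table-style rounding (half away from
zero, since `base::round()` banker's-rounds) with per-row decimal places,
and NNR is always recomputed from the *unrounded* precision. An empty
retrieval makes precision/NNR flagged-undefined (`NaN`) rather than zero —
an NNR of "infinitely many records per find" is meaningless, not large.

Published evaluation tables usually print only (n included, N retrieved,
sensitivity %, specificity %). Because the hidden cells are integers,
`back_derive_counts()` recovers them by nearest-integer rounding, and
`published_evaluations()` applies this to the twelve per-review rows of
the PF and Haynes filter evaluations, forward-checking every other printed
cell. Eleven of the sixty printed cells cannot be regenerated by *any*
rounding convention — e.g. one review's printed time-saved is provably
inconsistent with its own printed specificity for every possible D cell,
and one NNR is consistent only with a retrieval count that contradicts the
same row's specificity. These cells are recorded in the fixture's `flags`
column with the recomputed (internally consistent) value alongside the
printed one; tests assert exact reproduction of the other forty-nine and
pin the flagged set so that any regression in the reconstruction logic
surfaces.

## Pooling

`pool_proportions()` implements the classical proportion meta-analysis
chain: Freeman–Tukey double arcsine in its sum form
`asin√(e/(n+1)) + asin√((e+1)/(n+1))` with variance `1/(n+0.5)`,
DerSimonian–Laird moment estimate of τ², inverse-variance random-effects
weights, and Miller's harmonic-mean back-transform, matching the defaults
of the Stata `metaprop` tradition in which such evaluations were pooled.
Transformed values beyond the attainable range at the harmonic-mean n
(as an upper confidence limit can be) map to the boundary proportions 0
and 1. A logit route with boundary-only 0.5 continuity correction is
provided as an alternative. The sum-form transform is twice the half-sum
form some libraries use, with four times its variance; weights, estimates
and intervals are identical, and the test suite pins this equivalence
against `metafor` (τ² scales by exactly 4). Point-estimate invariants
(within study range, permutation invariance, duplication invariance in the
homogeneous case) are exercised as property tests; duplication exactness
is restricted to τ² = 0 because the DL degrees-of-freedom correction
shifts τ² slightly when heterogeneous studies are duplicated.

Pooling the six back-derived per-review sensitivities and specificities
reproduces the evaluation's overall 95% and 41%; tests allow ±2
percentage points because the original software and transform variant are
not fully specified, but the defaults land on the integers exactly.

## The synthetic corpus generator

`generate_corpus()` exists so every pipeline stage is testable offline. It
emulates the *structure* of a relative-recall evaluation: a relevant class
(default 73 records, the combined reference-set size) inside a larger
baseline (default 1,400, the order of a typical single-review retrieval),
with each signal term/heading planted independently per record at
class-specific probabilities. Defaults
(`default_signal_terms()`/`default_mesh_signal()`) use the filter's own
free-text terms and headings at rates chosen so an OR-filter over them
attains high (>95%) expected sensitivity and moderate specificity,
mirroring the observed performance regime. Background text is drawn from a
Zipf-like vocabulary whose head is ordinary function words — so, as in
real prose, the highest-document-frequency tokens are stopwords — and
whose tail is neutral pseudo-words that cannot collide with search terms.
Abstract lengths are Poisson; morphological variants
("prognostic"/"prognosis") are planted as distinct terms so truncation is
exercised. Generation is fully deterministic given `seed` (byte-identical
MEDLINE output), and the caller's RNG state is restored afterwards.

What it does *not* emulate — and what passing tests therefore do not
show about real data: correlated term occurrence (real methodological
vocabulary co-occurs), topic drift between reviews, indexing error in
MeSH assignment, journal/year structure, and free-text term variants
beyond the planted list. Closed-form expectations
(`expected_retrieval_pct()`, `100·(1−∏(1−pᵢ))`) hold only because of the
independence assumption; on real corpora they would be optimistic.

## Problem sizes and numerical choices

The test suite runs corpora of 40–250 records per class for engine and
statistics checks, a 200 + 2,000 corpus for the end-to-end
discovery-to-evaluation recovery check (planted strong terms must appear
in the top-20 ranking and the filter's sensitivity must land within 3
points of the closed form), and oracle-equivalence sweeps on corpora of
150–160 records — sizes at which a naive per-record AST walk is still an
independent, affordable oracle for the vectorized engine. Chi-square
values are cross-checked against both the closed-form 2×2 statistic and
the squared two-proportion z statistic at 1e-9 tolerance.

## Limitations

* The Ovid subset is intentional: no proximity operators (`adjN`), no
  `.mp`, no floating subheadings, no nested parentheses beyond line
  combos. Strategies using them fail to parse loudly rather than
  approximately.
* The RIS reader covers the common tag profile (TY/TI/T1/AB/N2/KW/ID/AN/
  PY/Y1/ER), not vendor extensions.
* Reconstructed 2×2 cells inherit the printed rows' rounding; where a
  published row is internally inconsistent, the package sides with
  arithmetic and flags the cell rather than reproducing the misprint.
* Pooled confidence intervals use the normal approximation on the
  transformed scale; no prediction intervals, REML or Paule–Mandel
  estimators are offered.
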