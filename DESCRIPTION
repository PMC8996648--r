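Package: filterlab
Title: Development and Evaluation of Bibliographic Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and evaluating methodological search
    filters for bibliographic databases. Reads MEDLINE flat-file and RIS
    records, parses and executes Ovid-dialect Boolean search strategies
    (including MeSH explosion and textword truncation) against local
    corpora, selects candidate filter terms by word-frequency and
    chi-square analysis, aggregates Delphi panel ratings under RAND/UCLA
    appropriateness rules, scores filters against reference sets by the
    relative recall method (sensitivity, specificity, precision, number
    needed to read, time saved), and pools per-review proportions by
    Freeman-Tukey double-arcsine random-effects meta-analysis. Ships the
    prognostic factor filter and the Haynes broad prognosis filter as
    built-in strategies, together with a synthetic MEDLINE-like corpus
    generator for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
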