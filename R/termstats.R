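#' Default English stopword list
#'
#' A compact list of function words excluded from unigram frequency
#' analysis and from bigram formation. The word-frequency tool the filter
#' methodology emulates uses an unpublished list, so this one is a
#' documented, configurable choice.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "also", "am",
    "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it",
    "its", "itself", "may", "me", "might", "more", "most", "must", "my",
    "no", "nor", "not", "of", "off", "on", "once", "only", "or", "other",
    "our", "ours", "out", "over", "own", "same", "she", "should", "so",
    "some", "such", "than", "that", "the", "their", "theirs", "them",
    "then", "there", "these", "they", "this", "those", "through", "to",
    "too", "under", "until", "up", "upon", "very", "was", "we", "were",
    "what", "when", "where", "which", "while", "who", "whom", "why", "will",
    "with", "within", "without", "would", "you", "your", "yours")
}

record_terms <- function(records, ngram_max, stopwords) {
  # per record: list(all = multiset of terms, uniq = set) over title+abstract
  lapply(seq_len(nrow(records)), function(i) {
    terms <- character()
    for (f in c("title", "abstract")) {
      toks <- tokenize1(records[[f]][i])
      keep <- !(toks %in% stopwords)
      terms <- c(terms, toks[keep])
      if (ngram_max >= 2 && length(toks) >= 2) {
        adj <- keep[-length(keep)] & keep[-1]
        if (any(adj)) {
          terms <- c(terms,
                     paste(toks[-length(toks)][adj], toks[-1][adj]))
        }
      }
    }
    terms
  })
}

#' Word-frequency analysis of titles and abstracts
#'
#' Counts lowercased, punctuation-stripped tokens of title plus abstract.
#' Stopwords are excluded from unigrams; bigrams are formed from pairs of
#' adjacent non-stopword tokens within a field.
#'
#' @param records A records tibble.
#' @param ngram_max 1 for unigrams only, 2 to add bigrams.
#' @param stopwords Stopword list; see [default_stopwords()].
#' @return A tibble with `term`, `doc_count` (records containing the term)
#'   and `occurrence_count` (total occurrences), sorted by `doc_count`
#'   then `occurrence_count` descending.
#' @examples
#' r <- bib_records(c("1", "2"), c("risk of risk", "cohort study"))
#' word_frequency(r)
#' @export
word_frequency <- function(records, ngram_max = 1,
                           stopwords = default_stopwords()) {
  records <- validate_records(records)
  stopifnot(ngram_max %in% 1:2)
  if (!nrow(records)) stop("empty corpus", call. = FALSE)
  per_doc <- record_terms(records, ngram_max, stopwords)
  occ <- table(unlist(per_doc, use.names = FALSE))
  doc <- table(unlist(lapply(per_doc, unique), use.names = FALSE))
  if (!length(occ)) {
    return(tibble::tibble(term = character(), doc_count = integer(),
                          occurrence_count = integer()))
  }
  out <- tibble::tibble(
    term = names(doc),
    doc_count = as.integer(doc),
    occurrence_count = as.integer(occ[names(doc)])
  )
  dplyr::arrange(out, dplyr::desc(.data$doc_count),
                 dplyr::desc(.data$occurrence_count), .data$term)
}

docs_with_term <- function(records, term, stopwords) {
  tt <- tokenize1(term)
  ngram_max <- length(tt)
  stopifnot(ngram_max %in% 1:2)
  per_doc <- record_terms(records, ngram_max, stopwords)
  key <- paste(tt, collapse = " ")
  vapply(per_doc, function(x) key %in% x, logical(1))
}

#' Chi-square discrimination of one term between two record sets
#'
#' Builds the 2x2 contingency table of document presence/absence of the
#' term in the positive (review-included) versus negative set and tests it
#' with Pearson's chi-square on 1 df (via [stats::chisq.test()]), with or
#' without the Yates continuity correction. A term absent from (or present
#' in) every record of both sets carries no information and is returned
#' with `chi2 = 0`, `p_value = 1`.
#'
#' @param term Unigram or bigram.
#' @param pos_records,neg_records Records tibbles; both non-empty.
#' @param yates Apply the continuity correction?
#' @param stopwords Stopword list used by the tokenizer (a stopword term
#'   can still be counted when passed explicitly as part of a bigram).
#' @return A one-row tibble: `term`, `pos_with`, `pos_total`, `neg_with`,
#'   `neg_total`, `chi2`, `p_value`.
#' @export
term_chi_square <- function(term, pos_records, neg_records, yates = FALSE,
                            stopwords = character()) {
  pos_records <- validate_records(pos_records)
  neg_records <- validate_records(neg_records)
  if (!nrow(pos_records) || !nrow(neg_records)) {
    stop("both record sets must be non-empty", call. = FALSE)
  }
  pw <- sum(docs_with_term(pos_records, term, stopwords))
  nw <- sum(docs_with_term(neg_records, term, stopwords))
  res <- chi2_2x2(pw, nrow(pos_records), nw, nrow(neg_records), yates = yates)
  tibble::tibble(term = term, pos_with = pw, pos_total = nrow(pos_records),
                 neg_with = nw, neg_total = nrow(neg_records),
                 chi2 = res[1], p_value = res[2])
}

chi2_2x2 <- function(pos_with, pos_total, neg_with, neg_total, yates = FALSE) {
  a <- pos_with; b <- pos_total - pos_with
  c <- neg_with; d <- neg_total - neg_with
  # degenerate column margin: term in none or in all records overall
  if (a + c == 0 || b + d == 0) return(c(0, 1))
  tab <- matrix(c(a, b, c, d), nrow = 2)
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  stat <- unname(ht$statistic)
  if (!is.finite(stat)) return(c(0, 1))
  c(stat, unname(ht$p.value))
}

#' Rank candidate filter terms by frequency and discrimination
#'
#' Candidate terms are drawn from the word-frequency analysis of the
#' positive set, ordered by positive-set document frequency with ties
#' broken by chi-square (descending, uncorrected Pearson) and then
#' lexicographically, and truncated to `top_n`. Screening for
#' *methodological* (versus clinical-content) terms is deliberately left
#' to the expert-panel stage.
#'
#' @inheritParams term_chi_square
#' @param top_n Number of terms to keep.
#' @param ngram_max Passed to [word_frequency()].
#' @return A tibble of at most `top_n` rows with the columns of
#'   [term_chi_square()].
#' @export
rank_candidate_terms <- function(pos_records, neg_records, top_n = 80,
                                 ngram_max = 1,
                                 stopwords = default_stopwords()) {
  stopifnot(top_n >= 1)
  pos_records <- validate_records(pos_records)
  neg_records <- validate_records(neg_records)
  if (!nrow(pos_records) || !nrow(neg_records)) {
    stop("both record sets must be non-empty", call. = FALSE)
  }
  wf <- word_frequency(pos_records, ngram_max = ngram_max,
                       stopwords = stopwords)
  if (!nrow(wf)) return(tibble::tibble(
    term = character(), pos_with = integer(), pos_total = integer(),
    neg_with = integer(), neg_total = integer(),
    chi2 = double(), p_value = double()))
  neg_doc <- record_terms(neg_records, ngram_max, stopwords)
  neg_tab <- table(unlist(lapply(neg_doc, unique), use.names = FALSE))
  neg_with <- as.integer(neg_tab[wf$term])
  neg_with[is.na(neg_with)] <- 0L
  stats <- t(mapply(chi2_2x2, wf$doc_count, nrow(pos_records),
                    neg_with, nrow(neg_records)))
  out <- tibble::tibble(
    term = wf$term,
    pos_with = wf$doc_count,
    pos_total = nrow(pos_records),
    neg_with = unname(neg_with),
    neg_total = nrow(neg_records),
    chi2 = stats[, 1],
    p_value = stats[, 2]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$pos_with),
                        dplyr::desc(.data$chi2), .data$term)
  head(out, top_n)
}
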