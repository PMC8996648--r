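#' Classify panel ratings of one term under RAND/UCLA appropriateness rules
#'
#' Ratings are integers on the 1-9 appropriateness scale. The term's
#' category follows the median tertile: median 7-9 is *appropriate*, 1-3
#' *inappropriate*, anything else (including half-integer medians falling
#' between tertiles) *uncertain*. The panel is in *disagreement* when at
#' least `ceiling(extreme_fraction * n)` ratings fall in 1-3 **and** at
#' least that many fall in 7-9; disagreement overrides the category to
#' uncertain.
#'
#' @param ratings Integer vector of at least 3 ratings in 1..9.
#' @param extreme_fraction Fraction of the panel that must sit in each
#'   extreme tertile to declare disagreement; the classic rule for panels
#'   larger than nine is one third.
#' @param term Optional term label carried through to the output.
#' @return A one-row tibble: `term`, `n`, `median`, `category` (factor:
#'   appropriate/uncertain/inappropriate), `disagreement`.
#' @examples
#' classify_term(rep(8, 15))
#' classify_term(c(rep(1, 7), rep(9, 8)))  # median 9 but split panel
#' @export
classify_term <- function(ratings, extreme_fraction = 1 / 3, term = NA_character_) {
  ratings <- as.numeric(ratings)
  if (length(ratings) < 3) stop("need at least 3 ratings", call. = FALSE)
  if (anyNA(ratings) || any(ratings < 1 | ratings > 9 | ratings != round(ratings))) {
    stop("ratings must be integers in 1..9", call. = FALSE)
  }
  stopifnot(extreme_fraction > 0, extreme_fraction <= 1)
  n <- length(ratings)
  med <- median(ratings)
  need <- ceiling(extreme_fraction * n)
  disagreement <- sum(ratings <= 3) >= need && sum(ratings >= 7) >= need
  category <- if (med >= 7) "appropriate"
  else if (med <= 3) "inappropriate"
  else "uncertain"
  if (disagreement && category == "appropriate") category <- "uncertain"
  if (disagreement && category == "inappropriate") category <- "uncertain"
  tibble::tibble(
    term = term, n = n, median = med,
    category = factor(category,
                      levels = c("appropriate", "uncertain", "inappropriate")),
    disagreement = disagreement
  )
}

#' Read a Delphi rating table
#'
#' Delimited text with columns `term`, `panelist`, `round`, `rating`
#' (header required; tab or comma delimited).
#'
#' @param path File path or literal text (see [read_records()]).
#' @return A tibble with those four columns, ratings validated to 1..9.
#' @export
read_ratings <- function(path) {
  lines <- read_input_lines(path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("term", "panelist", "round", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("rating table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$rating <- as.integer(df$rating)
  if (anyNA(df$rating) || any(df$rating < 1 | df$rating > 9)) {
    stop("ratings must be integers in 1..9", call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' Classify every term of a rating table for one round
#'
#' @param ratings A rating tibble as from [read_ratings()].
#' @param round Which round to classify; defaults to the final round.
#' @inheritParams classify_term
#' @return A tibble with one verdict row per term (see [classify_term()]),
#'   in order of first appearance.
#' @export
classify_round <- function(ratings, round = NULL, extreme_fraction = 1 / 3) {
  stopifnot(all(c("term", "panelist", "round", "rating") %in% names(ratings)))
  round <- round %||% max(ratings$round)
  rr <- ratings[ratings$round == round, ]
  if (!nrow(rr)) stop("no ratings for round ", round, call. = FALSE)
  terms <- unique(rr$term)
  n_pan <- length(unique(rr$panelist))
  counts <- table(rr$term)
  incomplete <- terms[counts[terms] < n_pan]
  if (length(incomplete)) {
    stop("round ", round, " is incomplete for term(s): ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(lapply(terms, function(tm) {
    classify_term(rr$rating[rr$term == tm],
                  extreme_fraction = extreme_fraction, term = tm)
  }))
}

#' Select filter terms from the final Delphi round
#'
#' A term enters the filter when its final-round verdict is *appropriate*
#' (median 7-9) without panel disagreement. Earlier rounds are accepted in
#' the table but do not influence selection.
#'
#' @inheritParams classify_round
#' @return Character vector of selected terms, in input order.
#' @export
select_filter_terms <- function(ratings, extreme_fraction = 1 / 3) {
  verdicts <- classify_round(ratings, extreme_fraction = extreme_fraction)
  verdicts$term[verdicts$category == "appropriate" & !verdicts$disagreement]
}
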