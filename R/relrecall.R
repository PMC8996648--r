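#' Confusion table for a filter against a reference set
#'
#' Cross-classifies the records of a baseline search result by whether the
#' filtered search retrieved them and whether they belong to the reference
#' set: `a` true positives, `b` false positives, `c` false negatives, `d`
#' true negatives. The relative-recall premise requires both the filtered
#' set and the reference set to lie inside the baseline set.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion table cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(setNames(as.integer(round(cells)), names(cells))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>  retrieved / not-retrieved x reference / other\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("retrieved", "not retrieved"),
                              c("reference", "non-reference")))
  print(m)
  invisible(x)
}

#' Build a confusion table from id sets
#'
#' @param baseline_ids Ids retrieved by the review's original (unfiltered)
#'   search.
#' @param filter_ids Ids retrieved with the filter ANDed in; must be a
#'   subset of `baseline_ids`.
#' @param reference A [reference_set()] whose ids must also fall inside
#'   `baseline_ids`.
#' @return A [confusion_table()] with `a + b + c + d == length(unique(baseline_ids))`.
#' @examples
#' build_confusion(as.character(1:10), c("1", "2", "3"),
#'                 reference_set("toy", c("1", "4")))
#' @export
build_confusion <- function(baseline_ids, filter_ids, reference) {
  stopifnot(inherits(reference, "reference_set"))
  baseline_ids <- unique(as.character(baseline_ids))
  filter_ids <- unique(as.character(filter_ids))
  stray_f <- setdiff(filter_ids, baseline_ids)
  if (length(stray_f)) {
    stop("filter ids outside the baseline search: ",
         paste(stray_f, collapse = ", "), call. = FALSE)
  }
  stray_r <- setdiff(reference$ids, baseline_ids)
  if (length(stray_r)) {
    stop("reference-set ids missing from the baseline search (relative ",
         "recall premise fails): ", paste(stray_r, collapse = ", "),
         call. = FALSE)
  }
  ref <- reference$ids
  confusion_table(
    a = length(intersect(filter_ids, ref)),
    b = length(setdiff(filter_ids, ref)),
    c = length(setdiff(ref, filter_ids)),
    d = length(baseline_ids) - length(union(filter_ids, ref))
  )
}

#' Retrieval performance metrics from a confusion table
#'
#' The five standard filter-performance statistics, all computed from the
#' raw cells and left unrounded:
#' \describe{
#'   \item{sensitivity}{`100 * a / (a + c)` — share of reference records
#'     retrieved.}
#'   \item{specificity}{`100 * d / (b + d)` — share of non-relevant
#'     records excluded.}
#'   \item{precision}{`100 * a / (a + b)` (positive predictive value);
#'     undefined when the filter retrieves nothing.}
#'   \item{nnr}{`100 / precision` — records to screen per relevant record.}
#'   \item{time_saved}{`100 * (c + d) / (a + b + c + d)` — share of the
#'     baseline result the filter removes from screening.}
#' }
#'
#' @param ct A [confusion_table()]; needs `a + c > 0` (a non-empty
#'   reference set) and `b + d > 0`.
#' @return A one-row tibble: `a`, `b`, `c`, `d`, `sensitivity`,
#'   `specificity`, `precision`, `nnr`, `time_saved`,
#'   `precision_defined`. When `a + b == 0`, `precision` and `nnr` are
#'   `NaN` and `precision_defined` is `FALSE`.
#' @examples
#' compute_metrics(confusion_table(7, 80, 0, 13))
#' @export
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  a <- ct$a; b <- ct$b; c <- ct$c; d <- ct$d
  if (a + c == 0) stop("empty reference set (a + c == 0)", call. = FALSE)
  if (b + d == 0) stop("no non-reference records (b + d == 0)", call. = FALSE)
  defined <- (a + b) > 0
  precision <- if (defined) 100 * a / (a + b) else NaN
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    sensitivity = 100 * a / (a + c),
    specificity = 100 * d / (b + d),
    precision = precision,
    nnr = if (defined && precision > 0) 100 / precision else NaN,
    time_saved = 100 * (c + d) / (a + b + c + d),
    precision_defined = defined
  )
}

#' Reconstruct a confusion table from a published summary row
#'
#' Published filter evaluations usually print only the reference-set size,
#' the baseline retrieval count, and percentage sensitivity/specificity.
#' Because the underlying cells are integers, they can be recovered by
#' nearest-integer rounding (half away from zero):
#' `a = round(sens * n / 100)`, `c = n - a`,
#' `d = round(spec * (N - n) / 100)`, `b = N - n - d`.
#'
#' @param included_n Reference-set size `n` (studies included in the
#'   review and present in the baseline search).
#' @param retrieved_total Baseline search size `N`.
#' @param sensitivity_pct,specificity_pct Printed percentages.
#' @return A [confusion_table()].
#' @examples
#' back_derive_counts(7, 100, 100, 14)   # -> a=7 b=80 c=0 d=13
#' @export
back_derive_counts <- function(included_n, retrieved_total,
                               sensitivity_pct, specificity_pct) {
  stopifnot(included_n > 0, included_n <= retrieved_total,
            sensitivity_pct >= 0, sensitivity_pct <= 100,
            specificity_pct >= 0, specificity_pct <= 100)
  a <- round_half_up(sensitivity_pct * included_n / 100)
  c <- included_n - a
  d <- round_half_up(specificity_pct * (retrieved_total - included_n) / 100)
  b <- retrieved_total - included_n - d
  if (min(a, b, c, d) < 0) {
    stop("back-derived cell is negative; the summary row is inconsistent",
         call. = FALSE)
  }
  confusion_table(a, b, c, d)
}

#' Evaluate a strategy against one review by relative recall
#'
#' Runs the strategy over the review's baseline records, builds the
#' confusion table against the reference set, and computes the metrics.
#'
#' @param baseline_records Records tibble of the review's original search
#'   result.
#' @param strategy An `ovid_strategy` (or strategy text).
#' @param mesh_tree A [mesh_tree()] for explosion (may be `NULL`).
#' @param reference A [reference_set()].
#' @return A list with elements `confusion` ([confusion_table()]) and
#'   `metrics` (tibble from [compute_metrics()]).
#' @export
evaluate_review <- function(baseline_records, strategy, mesh_tree = NULL,
                            reference) {
  baseline_records <- validate_records(baseline_records)
  hits <- apply_strategy(strategy, baseline_records, mesh_tree)
  ct <- build_confusion(baseline_records$id, as.character(hits), reference)
  list(confusion = ct, metrics = compute_metrics(ct))
}

#' Round metrics the way evaluation tables print them
#'
#' Sensitivity, specificity and time saved are rounded to the nearest
#' integer (half away from zero) unless printed with decimals; precision
#' is rounded to `precision_digits`; NNR is the nearest integer of
#' `100 / precision` computed from the *unrounded* precision.
#'
#' @param metrics One-row tibble from [compute_metrics()].
#' @param precision_digits Decimals to keep on precision.
#' @param sens_digits,spec_digits Decimals on sensitivity/specificity.
#' @return A one-row tibble of display-rounded values.
#' @export
display_metrics <- function(metrics, precision_digits = 0,
                            sens_digits = 0, spec_digits = 0) {
  tibble::tibble(
    sensitivity = round_half_up(metrics$sensitivity, sens_digits),
    specificity = round_half_up(metrics$specificity, spec_digits),
    precision = round_half_up(metrics$precision, precision_digits),
    nnr = round_half_up(metrics$nnr),
    time_saved = round_half_up(metrics$time_saved)
  )
}
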