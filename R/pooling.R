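#' Transform a proportion for meta-analysis
#'
#' Two variance-stabilizing transforms for pooling proportions:
#'
#' * `ft_dl` — Freeman-Tukey double arcsine,
#'   `t = asin(sqrt(e / (n + 1))) + asin(sqrt((e + 1) / (n + 1)))` with
#'   within-study variance `1 / (n + 0.5)`. Defined at both boundaries
#'   without any continuity correction.
#' * `logit_dl` — logit `log(p / (1 - p))` with variance
#'   `1/e + 1/(n - e)`; a 0.5 continuity correction is applied to both
#'   cells only when the study sits on a boundary (`e == 0` or `e == n`).
#'
#' @param events Number of events (0..total).
#' @param total Study size (> 0).
#' @param method `"ft_dl"` or `"logit_dl"`.
#' @return Named numeric vector `c(t = , variance = )`.
#' @examples
#' transform_proportion(5, 16)  # ~ c(t = 1.209, variance = 1/16.5)
#' @export
transform_proportion <- function(events, total, method = c("ft_dl", "logit_dl")) {
  method <- match.arg(method)
  stopifnot(events >= 0, events <= total)
  if (total <= 0) stop("study total must be positive", call. = FALSE)
  if (method == "ft_dl") {
    t <- asin(sqrt(events / (total + 1))) + asin(sqrt((events + 1) / (total + 1)))
    c(t = t, variance = 1 / (total + 0.5))
  } else {
    e <- events; n <- total
    if (e == 0 || e == n) { e <- e + 0.5; n <- n + 1 }
    c(t = log(e / (n - e)), variance = 1 / e + 1 / (n - e))
  }
}

# Miller's harmonic-mean back-transform for the double arcsine (sum form).
# Values beyond the transforms of p = 0 and p = 1 at the harmonic mean n
# map to the boundary proportions.
ft_back_transform <- function(t, harmonic_n) {
  n <- harmonic_n
  tmin <- asin(sqrt(1 / (n + 1)))          # transform of 0 events out of n
  tmax <- asin(sqrt(n / (n + 1))) + pi / 2 # transform of n events out of n
  s <- sin(t)
  inner <- s + (s - 1 / s) / n
  inner <- pmin(pmax(inner, -1), 1)
  p <- 0.5 * (1 - sign(cos(t)) * sqrt(1 - inner^2))
  p[t <= tmin] <- 0
  p[t >= tmax] <- 1
  p
}

#' Pool proportions by random-effects meta-analysis
#'
#' Inverse-variance random-effects pooling on the transformed scale with
#' the DerSimonian-Laird moment estimator of the between-study variance
#' tau-squared. The pooled value and its 95% normal-approximation
#' confidence interval are back-transformed (for the Freeman-Tukey
#' transform, with Miller's formula using the harmonic mean of the study
#' sizes) and expressed as percentages clamped to \[0, 100\]. A single
#' study is returned as its own proportion and CI.
#'
#' @param studies A data frame with columns `events` and `total` (and
#'   optionally `label`), one row per study.
#' @param method `"ft_dl"` (default) or `"logit_dl"`; see
#'   [transform_proportion()].
#' @param conf_level Confidence level of the interval.
#' @return An object of class `pooled_estimate`: list with `estimate`,
#'   `ci_low`, `ci_high` (percent), `tau2` (transformed scale), `method`,
#'   `k`, and a `studies` tibble with per-study proportions, transforms
#'   and weights.
#' @examples
#' pool_proportions(data.frame(events = c(5, 5, 5), total = c(10, 10, 10)))
#' @export
pool_proportions <- function(studies, method = c("ft_dl", "logit_dl"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(is.data.frame(studies),
            all(c("events", "total") %in% names(studies)))
  k <- nrow(studies)
  if (k < 1) stop("need at least one study", call. = FALSE)
  if (any(studies$events > studies$total) || any(studies$total <= 0)) {
    stop("each study needs 0 <= events <= total, total > 0", call. = FALSE)
  }
  tv <- t(mapply(transform_proportion, studies$events, studies$total,
                 MoreArgs = list(method = method)))
  ti <- tv[, "t"]; vi <- tv[, "variance"]
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (k == 1) {
    mu <- ti[1]; se <- sqrt(vi[1]); tau2 <- 0; w_re <- 1 / vi
  } else {
    w <- 1 / vi
    mu_fe <- sum(w * ti) / sum(w)
    q <- sum(w * (ti - mu_fe)^2)
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_dl)
    w_re <- 1 / (vi + tau2)
    mu <- sum(w_re * ti) / sum(w_re)
    se <- sqrt(1 / sum(w_re))
  }
  lo <- mu - z * se
  hi <- mu + z * se

  if (method == "ft_dl") {
    hn <- k / sum(1 / studies$total)
    back <- function(x) 100 * ft_back_transform(x, hn)
  } else {
    back <- function(x) 100 * stats::plogis(x)
  }
  est <- back(mu)
  ci <- sort(c(back(lo), back(hi)))
  structure(list(
    estimate = min(max(est, 0), 100),
    ci_low = min(max(ci[1], 0), 100),
    ci_high = min(max(ci[2], 0), 100),
    tau2 = tau2,
    method = method,
    k = k,
    studies = tibble::tibble(
      label = if ("label" %in% names(studies)) as.character(studies$label)
              else paste0("study_", seq_len(k)),
      events = studies$events, total = studies$total,
      proportion = 100 * studies$events / studies$total,
      t = unname(ti), variance = unname(vi), weight = unname(w_re)
    )
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "<pooled_estimate> %s, k = %d: %.1f%% (95%% CI %.1f-%.1f), tau2 = %.4f\n",
    x$method, x$k, x$estimate, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}

#' Forest plot of per-study proportions and the pooled estimate
#'
#' Per-study proportions with exact binomial confidence intervals, and the
#' pooled random-effects estimate as a diamond-coloured summary row.
#'
#' @param pooled A `pooled_estimate` from [pool_proportions()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_forest <- function(pooled, title = "Pooled proportion") {
  stopifnot(inherits(pooled, "pooled_estimate"))
  st <- pooled$studies
  ci <- t(mapply(function(e, n) {
    bt <- stats::binom.test(e, n)
    100 * bt$conf.int
  }, st$events, st$total))
  df <- tibble::tibble(
    label = factor(c(st$label, "Pooled"),
                   levels = rev(c(st$label, "Pooled"))),
    p = c(st$proportion, pooled$estimate),
    lo = c(ci[, 1], pooled$ci_low),
    hi = c(ci[, 2], pooled$ci_high),
    pooled = c(rep(FALSE, nrow(st)), TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$label)) +
    ggplot2::geom_vline(xintercept = pooled$estimate, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled,
                                     size = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(15, 18), guide = "none") +
    ggplot2::scale_size_manual(values = c(2, 5), guide = "none") +
    ggplot2::labs(x = "Proportion (%)", y = NULL, title = title) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}
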