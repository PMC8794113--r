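#' Wilson score confidence interval for a proportion
#'
#' Closed-form Wilson bounds
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`
#' with `z` the standard-normal quantile for the requested level.  The
#' interval always contains the point estimate and respects the \[0, 1\]
#' range, with better small-sample behavior than the Wald interval.
#'
#' @param p_hat Observed proportion in \[0, 1\].
#' @param n Sample size (>= 1).
#' @param level Confidence level (default 0.95).
#' @return An object of class `wilson_interval`: list with `estimate`,
#'   `lower`, `upper`, `n`, `level` and `scale = "proportion"`.
#' @examples
#' wilson_interval(0.5, 100)
#' @export
wilson_interval <- function(p_hat, n, level = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_invalid("n must be >= 1")
  if (length(p_hat) != 1) stop_invalid("p_hat must be a single value")
  if (is.na(p_hat)) {
    return(structure(
      list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
           n = as.integer(n), level = level, scale = "proportion"),
      class = "wilson_interval"
    ))
  }
  if (p_hat < 0 || p_hat > 1) stop_invalid("p_hat must lie in [0, 1]")
  if (level <= 0 || level >= 1) stop_invalid("level must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  # clamp away one-ulp excursions: at p_hat = 0 or 1 the exact bound
  # coincides with the estimate and floating arithmetic can overshoot
  lower <- min(max(center - half, 0), p_hat)
  upper <- max(min(center + half, 1), p_hat)
  structure(
    list(estimate = p_hat, lower = lower, upper = upper,
         n = as.integer(n), level = level, scale = "proportion"),
    class = "wilson_interval"
  )
}

#' @export
print.wilson_interval <- function(x, ...) {
  cat(sprintf(
    "<wilson_interval> %s scale: %.4f (%.4f, %.4f), n = %d, level = %g\n",
    x$scale, x$estimate, x$lower, x$upper, x$n, x$level
  ))
  invisible(x)
}

#' Wilson interval for a reported performance metric
#'
#' ECE, accuracy and F-score live on \[0, 1\] and are treated directly as
#' proportions.  MCC lives on \[-1, 1\] and is mapped affinely to the
#' proportion scale via `(mcc + 1) / 2`; the Wilson bounds are computed
#' there and mapped back with `2p - 1`, which keeps the interval inside
#' \[-1, 1\] and preserves the boundary (an MCC of exactly 1 has upper
#' bound 1).  An `NA` metric yields an `NA` interval.
#'
#' The affine treatment of MCC is an interpretation: a Wilson interval is
#' a proportion method and is applied here to non-proportion summaries
#' exactly as reported study tables do, without a distributional claim.
#'
#' @param value Metric value (or `NA`).
#' @param metric One of `"ece"`, `"mcc"`, `"accuracy"`, `"f"`.
#' @param n Evaluation sample size.
#' @param level Confidence level.
#' @return A `wilson_interval`; for MCC the `scale` field is `"mcc"`.
#' @examples
#' metric_interval(0.61, "mcc", n = 200)
#' @export
metric_interval <- function(value, metric = c("ece", "mcc", "accuracy", "f"),
                            n, level = 0.95) {
  metric <- match.arg(metric)
  if (metric != "mcc") {
    return(wilson_interval(value, n, level))
  }
  if (!is.na(value) && (value < -1 || value > 1)) {
    stop_invalid("mcc must lie in [-1, 1]")
  }
  wi <- wilson_interval(if (is.na(value)) NA_real_ else (value + 1) / 2,
                        n, level)
  structure(
    list(estimate = value,
         lower = 2 * wi$lower - 1,
         upper = 2 * wi$upper - 1,
         n = wi$n, level = level, scale = "mcc"),
    class = "wilson_interval"
  )
}

#' Significance call from two confidence intervals
#'
#' Two estimates are declared significantly different if and only if
#' their confidence intervals do not overlap -- the only procedure the
#' reported interval tables support.  Non-overlap of two 95% intervals is
#' conservative relative to a p < 0.05 test of the difference.
#'
#' @param a,b `wilson_interval` objects at the same confidence level.
#' @return List with `significant` (logical; `NA` if either interval is
#'   `NA`) and `direction` (sign of `a$estimate - b$estimate`).
#' @examples
#' significant_difference(wilson_interval(0.15, 50), wilson_interval(0.3, 50))
#' @export
significant_difference <- function(a, b) {
  stopifnot(inherits(a, "wilson_interval"), inherits(b, "wilson_interval"))
  if (!isTRUE(all.equal(a$level, b$level))) {
    stop_invalid("intervals have different confidence levels")
  }
  if (is.na(a$estimate) || is.na(b$estimate)) {
    return(list(significant = NA, direction = NA_real_))
  }
  list(
    significant = a$upper < b$lower || b$upper < a$lower,
    direction = sign(a$estimate - b$estimate)
  )
}
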