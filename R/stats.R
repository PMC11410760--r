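# Pairwise sensitivity-difference significance testing: standard errors
# recovered from 95% CI widths, a two-sample Z statistic, and two-tailed
# p-values against alpha = 0.05. Confidence intervals use the Wilson score
# interval, which stays well-behaved near 0 and 1. The Z test treats the
# two sensitivities as independent; shared-test-set pairing is not modeled.

#' Standard error from a 95% confidence interval
#'
#' `SE = (CI_upper - CI_lower) / (2 * 1.96)`.
#'
#' @param ci_lower,ci_upper Interval bounds with `ci_upper >= ci_lower`.
#' @return The implied standard error.
#' @export
se_from_ci <- function(ci_lower, ci_upper) {
  if (any(ci_upper < ci_lower)) stop("inverted confidence interval")
  (ci_upper - ci_lower) / (2 * 1.96)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' A sensitivity estimate with its confidence interval
#'
#' @param sensitivity Point estimate in \[0, 1\].
#' @param ci_lower,ci_upper 95% CI bounds bracketing the estimate.
#' @param n_positive Number of positive cases behind the estimate
#'   (informational).
#' @return An object of class `sensitivity_estimate`.
#' @export
sensitivity_estimate <- function(sensitivity, ci_lower, ci_upper,
                                 n_positive = NA_integer_) {
  stopifnot(ci_lower <= sensitivity + 1e-12,
            sensitivity <= ci_upper + 1e-12,
            ci_lower >= 0, ci_upper <= 1)
  structure(list(sensitivity = unname(sensitivity),
                 ci_lower = unname(ci_lower), ci_upper = unname(ci_upper),
                 n_positive = n_positive),
            class = "sensitivity_estimate")
}

#' Estimate sensitivity with a Wilson CI from counts
#'
#' @param tp,fn True-positive and false-negative counts.
#' @param level Confidence level.
#' @return A [sensitivity_estimate()].
#' @export
estimate_sensitivity <- function(tp, fn, level = 0.95) {
  n <- tp + fn
  ci <- binomial_ci(tp, n, level)
  sensitivity_estimate(tp / n, ci[1L], ci[2L], n_positive = n)
}

#' Compare two sensitivity estimates
#'
#' `delta = s_b - s_a`, combined SE `sqrt(SE_a^2 + SE_b^2)` with each SE
#' recovered from its CI width, `Z = delta / SE`, two-tailed p under the
#' standard normal; significant iff `p < alpha`.
#'
#' @param est_a,est_b [sensitivity_estimate()]s.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `comparison_result`: list with
#'   delta_sensitivity, delta_se, z, p, significant.
#' @export
compare_sensitivities <- function(est_a, est_b, alpha = 0.05) {
  se_a <- se_from_ci(est_a$ci_lower, est_a$ci_upper)
  se_b <- se_from_ci(est_b$ci_lower, est_b$ci_upper)
  delta_se <- sqrt(se_a^2 + se_b^2)
  if (delta_se == 0) stop("undefined Z: both standard errors are zero")
  delta <- est_b$sensitivity - est_a$sensitivity
  z <- delta / delta_se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(delta_sensitivity = delta, delta_se = delta_se, z = z,
                 p = p, significant = p < alpha),
            class = "comparison_result")
}

#' All pairwise sensitivity comparisons
#'
#' @param estimates Named list of [sensitivity_estimate()]s (>= 2, unique
#'   names).
#' @param alpha Significance level.
#' @return A data.frame with one row per unordered pair: model_a, model_b,
#'   delta_sensitivity, delta_se, z, p, significant.
#' @export
pairwise_panel <- function(estimates, alpha = 0.05) {
  if (length(estimates) < 2L) stop("need at least two estimates")
  nms <- names(estimates)
  if (is.null(nms) || anyDuplicated(nms)) stop("estimates need unique names")
  pairs <- utils::combn(length(estimates), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cr <- compare_sensitivities(estimates[[i]], estimates[[j]], alpha)
    data.frame(model_a = nms[i], model_b = nms[j],
               delta_sensitivity = cr$delta_sensitivity,
               delta_se = cr$delta_se, z = cr$z, p = cr$p,
               significant = cr$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
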