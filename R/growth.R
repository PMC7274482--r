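#' Time-to-threshold growth-rate estimate from an OD curve
#'
#' Assumes exponential growth from the known initial density `od0` up to a
#' threshold OD and estimates the per-capita rate as
#' `r = log(threshold / od0) / t_cross`, where `t_cross` is the first
#' crossing time of the threshold, found by linear interpolation between
#' samples.  No lag correction is applied: a lag phase lengthens the
#' crossing time and is implicitly absorbed into a lower rate estimate.
#'
#' @param times sampling times; the returned rate is per unit of this time
#'   axis (hours in, 1/hour out).
#' @param od background-subtracted optical densities; small negative values
#'   are clipped to zero with a warning.
#' @param od0 the known initial OD (equalized OD divided by the inoculum
#'   dilution factor); must be below `threshold`.
#' @param threshold threshold OD (default 0.1).
#' @return The growth rate in 1/(time unit).
#' @examples
#' t <- seq(0, 40, by = 0.25)
#' estimate_growth_rate(t, 1e-3 * exp(0.46 * t), od0 = 1e-3) # ~0.46
#' @export
estimate_growth_rate <- function(times, od, od0, threshold = 0.1) {
  if (length(times) != length(od) || length(times) < 2) {
    stop_lv("lvdilute_invalid_curve", "times and od must have equal length >= 2")
  }
  if (any(diff(times) <= 0)) {
    stop_lv("lvdilute_invalid_curve", "times must be strictly increasing")
  }
  if (any(od < 0)) {
    warning("negative OD values clipped to 0 (background over-subtraction)")
    od <- pmax(od, 0)
  }
  if (!is.finite(od0) || od0 <= 0 || od0 >= threshold) {
    stop_lv("lvdilute_invalid_curve", "od0 must be positive and below the threshold")
  }
  if (od[1] >= threshold) {
    stop_lv("lvdilute_invalid_curve", "curve starts at or above the threshold")
  }
  i <- which(od >= threshold)[1]
  if (is.na(i)) {
    stop_lv("lvdilute_no_growth", sprintf("curve never crosses threshold OD %g", threshold))
  }
  t_cross <- times[i - 1] + (threshold - od[i - 1]) / (od[i] - od[i - 1]) *
    (times[i] - times[i - 1])
  log(threshold / od0) / t_cross
}

#' Aggregate per-replicate growth-rate estimates
#'
#' Arithmetic mean and standard error across replicate curves, as used when
#' averaging time-to-threshold estimates over starting densities and
#' replicates.
#'
#' @param estimates numeric vector of per-replicate rates.
#' @param threshold threshold OD recorded with the estimate.
#' @return A list of class `lv_growth_rate` with `estimate` (mean), `sem`
#'   (`sd/sqrt(n)`; `NA` for a single replicate), `n`, `replicates`,
#'   `threshold`.
#' @export
aggregate_growth_rates <- function(estimates, threshold = 0.1) {
  estimates <- as.numeric(estimates)
  if (!length(estimates)) stop_lv("lvdilute_invalid_curve", "no estimates to aggregate")
  n <- length(estimates)
  structure(list(estimate = mean(estimates),
                 sem = if (n > 1) sd(estimates) / sqrt(n) else NA_real_,
                 n = n, replicates = estimates, threshold = threshold),
            class = "lv_growth_rate")
}

#' @export
print.lv_growth_rate <- function(x, ...) {
  cat(sprintf("Growth rate: %.4g +/- %.3g (SEM, n = %d), threshold OD %g\n",
              x$estimate, x$sem, x$n, x$threshold))
  invisible(x)
}
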