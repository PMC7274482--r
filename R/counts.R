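check_counts <- function(...) {
  cts <- list(...)
  for (x in cts) {
    if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
      stop_lv("lvdilute_invalid_counts", "colony counts must be non-negative integers")
    }
  }
  invisible(TRUE)
}

#' Posterior-mean species fraction from colony counts
#'
#' With `a` colonies of one species and `b` of the other, the fraction of
#' the first species under a uniform (Bayes') prior has posterior
#' `Beta(a + 1, b + 1)`; the posterior mean is `(a + 1) / (a + b + 2)`.
#' The raw ratio `a / (a + b)` is available via `fraction_raw()` for
#' plotting parity.
#'
#' @param a,b non-negative integer colony counts (vectorized).
#' @return Posterior-mean fraction of the first species.
#' @examples
#' fraction_estimate(49, 0) # 50/51
#' fraction_estimate(0, 0)  # 0.5 (no data, uniform prior)
#' @export
fraction_estimate <- function(a, b) {
  check_counts(a, b)
  (a + 1) / (a + b + 2)
}

#' @rdname fraction_estimate
#' @export
fraction_raw <- function(a, b) {
  check_counts(a, b)
  ifelse(a + b > 0, a / (a + b), NA_real_)
}

#' Beta-posterior standard deviation of a species fraction
#'
#' The error bar attached to a plated fraction: the standard deviation of
#' the `Beta(a + 1, b + 1)` posterior,
#' \deqn{\sigma = \sqrt{\frac{(a+1)(b+1)}{(a+b+2)^2\,(a+b+3)}}.}
#' It is symmetric in the two counts and shrinks as the plating deepens.
#'
#' @inheritParams fraction_estimate
#' @return The posterior SD.
#' @examples
#' fraction_sd(0, 0)   # 1/sqrt(12)
#' fraction_sd(49, 49) # ~0.0498
#' @export
fraction_sd <- function(a, b) {
  check_counts(a, b)
  sqrt((a + 1) * (b + 1) / ((a + b + 2)^2 * (a + b + 3)))
}

#' Annotate a long-format colony-count table with fraction statistics
#'
#' For each plating (grouping by the supplied key columns) computes, per
#' species, the raw fraction, the beta-posterior mean and the posterior SD,
#' treating each species against the pooled rest (which reduces to the
#' two-species formulas for pairs).
#'
#' @param counts data frame with at least `species` and `colonies` columns.
#' @param by character vector of grouping columns identifying one plating
#'   (default `c("day", "condition", "replicate")`, intersected with what is
#'   present).
#' @return The input with `fraction`, `fraction_posterior` and `sigma`
#'   columns appended.
#' @export
annotate_count_table <- function(counts,
                                 by = c("day", "condition", "replicate")) {
  if (!all(c("species", "colonies") %in% names(counts))) {
    stop_lv("lvdilute_invalid_counts", "counts needs 'species' and 'colonies' columns")
  }
  by <- intersect(by, names(counts))
  check_counts(counts$colonies)
  key <- if (length(by)) interaction(counts[by], drop = TRUE) else factor(rep(1, nrow(counts)))
  total <- ave(counts$colonies, key, FUN = sum)
  rest <- total - counts$colonies
  counts$fraction <- fraction_raw(counts$colonies, rest)
  counts$fraction_posterior <- fraction_estimate(counts$colonies, rest)
  counts$sigma <- fraction_sd(counts$colonies, rest)
  counts
}
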