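#' Community parameters for Lotka-Volterra competition
#'
#' Bundles per-species maximum growth rates `r`, the pairwise competition
#' matrix `alpha` and optional carrying capacities `K` into a validated
#' object.  Abundances in this package are always normalized by carrying
#' capacity, so the diagonal of `alpha` is fixed at 1 and `K` (in OD units)
#' is used only to convert to and from OD-scale synthetic data.
#'
#' The package's canonical time unit is days.  Rates supplied in 1/hour
#' (`unit = "per_hour"`) are converted on ingest; the original unit is
#' recorded in the returned object.
#'
#' @param r numeric vector of per-species maximum growth rates, strictly
#'   positive.
#' @param alpha square numeric matrix of dimensionless competition
#'   coefficients; `alpha[i, j]` is the inhibitory effect of species `j` on
#'   species `i`, relative to i's self-inhibition.  Entries must be
#'   non-negative and finite, the diagonal exactly 1.
#' @param species optional character vector of species names; defaults to
#'   `sp1`, `sp2`, ...
#' @param K optional per-species carrying capacity in OD units (used only by
#'   the synthetic-data generator).
#' @param unit unit of `r`: `"per_day"` (default, canonical) or
#'   `"per_hour"`.
#' @return An object of class `lv_params`: a list with elements `species`,
#'   `r` (1/day), `alpha`, `K`, `unit_in`.
#' @examples
#' p <- lv_params(r = c(0.7, 0.3), alpha = matrix(c(1, 1.6, 0.7, 1), 2, 2,
#'                byrow = TRUE), species = c("Pp", "Pv"), unit = "per_hour")
#' p
#' @export
lv_params <- function(r, alpha, species = NULL, K = NULL,
                      unit = c("per_day", "per_hour")) {
  unit <- match.arg(unit)
  r <- as.numeric(r)
  n <- length(r)
  if (n < 1) stop_lv("lvdilute_invalid_params", "at least one species required")
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop_lv("lvdilute_invalid_params", "all growth rates must be finite and strictly positive")
  }
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != n || ncol(alpha) != n) {
    stop_lv("lvdilute_invalid_params", sprintf(
      "alpha must be a %d x %d square matrix (got %d x %d)",
      n, n, nrow(alpha), ncol(alpha)))
  }
  if (any(!is.finite(alpha)) || any(alpha < 0)) {
    stop_lv("lvdilute_invalid_params", "alpha entries must be finite and non-negative")
  }
  if (any(abs(diag(alpha) - 1) > 1e-12)) {
    stop_lv("lvdilute_invalid_params",
            "diagonal of alpha must be exactly 1 (abundances are carrying-capacity normalized)")
  }
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  species <- as.character(species)
  if (length(species) != n || anyDuplicated(species)) {
    stop_lv("lvdilute_invalid_params", "species names must be unique and match length(r)")
  }
  if (!is.null(K)) {
    K <- as.numeric(K)
    if (length(K) != n || any(!is.finite(K)) || any(K <= 0)) {
      stop_lv("lvdilute_invalid_params", "K must be positive and of length n when given")
    }
  }
  if (unit == "per_hour") r <- r * 24
  dimnames(alpha) <- list(species, species)
  structure(
    list(species = species, r = setNames(r, species), alpha = alpha,
         K = if (is.null(K)) NULL else setNames(K, species), unit_in = unit),
    class = "lv_params"
  )
}

#' @export
print.lv_params <- function(x, ...) {
  n <- length(x$species)
  cat(sprintf("Lotka-Volterra community parameters (%d species)\n", n))
  cat("  growth rates r (1/day):\n")
  print(round(x$r, 4))
  cat("  competition matrix alpha (row = affected species):\n")
  print(round(x$alpha, 4))
  if (!is.null(x$K)) {
    cat("  carrying capacities K (OD units):\n")
    print(round(x$K, 4))
  }
  invisible(x)
}

n_species <- function(params) length(params$species)

assert_lv_params <- function(params) {
  if (!inherits(params, "lv_params")) {
    stop_lv("lvdilute_invalid_params", "expected an 'lv_params' object; see ?lv_params")
  }
  invisible(params)
}
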