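#' Effective competition coefficient under added mortality
#'
#' A community-wide death rate `delta` can be absorbed into the
#' Lotka-Volterra competition model by rescaling abundances, which turns the
#' competition coefficient `alpha_ij` into an effective coefficient
#' \deqn{\tilde\alpha_{ij} = \alpha_{ij}\,\frac{1 - \delta/r_j}{1 - \delta/r_i},}
#' valid while `delta` is below both growth rates.  The position of the
#' effective coefficients relative to 1 determines the competitive outcome,
#' so increasing mortality moves a pair across the phase diagram (it favors
#' the faster grower).
#'
#' @param alpha_ij dimensionless competition coefficient (effect of j on i).
#' @param r_i,r_j maximum growth rates of the affected species i and the
#'   competitor j, in 1/day.
#' @param delta community-wide mortality rate, 1/day; must satisfy
#'   `0 <= delta < min(r_i, r_j)`.
#' @return The effective coefficient, same shape as `alpha_ij`.
#' @seealso [critical_delta()], [classify_outcome()], [reparametrize_params()]
#' @examples
#' reparametrize(1.5, r_i = 1, r_j = 0.5, delta = 0.25) # 1
#' @export
reparametrize <- function(alpha_ij, r_i, r_j, delta) {
  check_washout(c(r_i, r_j), delta)
  alpha_ij * (1 - delta / r_j) / (1 - delta / r_i)
}

check_washout <- function(r, delta, species = NULL) {
  if (length(delta) != 1 || !is.finite(delta) || delta < 0) {
    stop_lv("lvdilute_invalid_delta", "delta must be a single finite value >= 0")
  }
  bad <- which(delta >= r)
  if (length(bad)) {
    who <- if (is.null(species)) paste0("species ", bad) else species[bad]
    stop_lv("lvdilute_washout", sprintf(
      "washout: mortality delta = %.4g/day meets or exceeds the growth rate of %s (net growth r - delta <= 0)",
      delta, paste(who, collapse = ", ")), species = who)
  }
  invisible(TRUE)
}

#' Reparametrize a whole community
#'
#' Applies the mortality rescaling to every pairwise coefficient and growth
#' rate, returning an equivalent mortality-free community: effective rates
#' `r - delta` and effective coefficients
#' `alpha[i, j] * (1 - delta/r_j) / (1 - delta/r_i)`.  Integrating the
#' effective model and mapping abundances back through
#' `N_i = Ntilde_i * (1 - delta/r_i)` reproduces the original dynamics.
#'
#' @param params an [lv_params] object.
#' @param delta mortality rate, 1/day, below every growth rate.
#' @return An `lv_params` object with effective rates and coefficients.
#' @export
reparametrize_params <- function(params, delta) {
  assert_lv_params(params)
  check_washout(params$r, delta, params$species)
  f <- 1 - delta / params$r            # per-species rescaling N = Ntilde * f
  at <- params$alpha * outer(1 / f, f) # at[i,j] = alpha[i,j] * f_j / f_i
  diag(at) <- 1
  lv_params(r = params$r - delta, alpha = at, species = params$species,
            K = params$K)
}

#' Classify the two-species competitive outcome
#'
#' In the mortality-free (or reparametrized) Lotka-Volterra model the
#' outcome depends only on where the two competition coefficients sit
#' relative to 1: both below 1 gives stable coexistence, both above 1 gives
#' bistability (two alternative exclusion states separated by an unstable
#' interior fraction), and exactly one above 1 gives competitive exclusion of
#' the suppressed species.
#'
#' @param alpha_tilde_ij effective coefficient measuring inhibition of
#'   species i by species j.
#' @param alpha_tilde_ji effective coefficient measuring inhibition of
#'   species j by species i.
#' @param boundary_tol half-width of the degenerate band around 1 within
#'   which classification is refused (the outcome is discontinuous there).
#' @return An object of class `lv_outcome`: list with `label` (one of
#'   `"COEXISTENCE"`, `"BISTABILITY"`, `"EXCLUSION_I_WINS"`,
#'   `"EXCLUSION_J_WINS"`), `stable_states` (equilibrium fraction(s) of
#'   species i) and `unstable_state` (unstable interior fraction of species
#'   i, or `NA`).
#' @examples
#' classify_outcome(0.5, 0.7)$label # coexistence
#' classify_outcome(1.5, 2.0)$label # bistability
#' @export
classify_outcome <- function(alpha_tilde_ij, alpha_tilde_ji,
                             boundary_tol = 1e-9) {
  a <- alpha_tilde_ij
  b <- alpha_tilde_ji
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop_lv("lvdilute_invalid_params", "effective coefficients must be finite and positive")
  }
  if (abs(a - 1) < boundary_tol || abs(b - 1) < boundary_tol) {
    stop_lv("lvdilute_degenerate_boundary", sprintf(
      "degenerate outcome: an effective coefficient is within %g of 1; perturb or report the boundary explicitly",
      boundary_tol))
  }
  interior <- function() {
    # interior equilibrium fractions of (i, j) in the rescaled model
    ni <- (1 - a) / (1 - a * b)
    nj <- (1 - b) / (1 - a * b)
    ni / (ni + nj)
  }
  if (a < 1 && b < 1) {
    out <- list(label = "COEXISTENCE", stable_states = interior(),
                unstable_state = NA_real_)
  } else if (a > 1 && b > 1) {
    out <- list(label = "BISTABILITY", stable_states = c(0, 1),
                unstable_state = interior())
  } else if (a > 1) {
    # species i is suppressed -> j wins
    out <- list(label = "EXCLUSION_J_WINS", stable_states = 0,
                unstable_state = NA_real_)
  } else {
    out <- list(label = "EXCLUSION_I_WINS", stable_states = 1,
                unstable_state = NA_real_)
  }
  structure(out, class = "lv_outcome")
}

#' @export
print.lv_outcome <- function(x, ...) {
  cat("Competitive outcome:", x$label, "\n")
  cat("  stable state(s), fraction of species i:",
      paste(signif(x$stable_states, 4), collapse = ", "), "\n")
  if (!is.na(x$unstable_state)) {
    cat("  unstable interior fraction (separatrix):",
        signif(x$unstable_state, 4), "\n")
  }
  invisible(x)
}

#' Interior equilibrium of a two-species pair under mortality
#'
#' Solves for the interior fixed point of the reparametrized model, maps it
#' back to the original normalized abundances via
#' `N_i = Ntilde_i * (1 - delta/r_i)`, and decides local stability from the
#' eigenvalues of the 2x2 community Jacobian at the point.
#'
#' @param params a two-species [lv_params] object.
#' @param delta mortality rate, 1/day.
#' @return A list of class `lv_equilibrium` with `abundances` (named,
#'   normalized), `stable` (logical), and `eigenvalues`.
#' @export
interior_fixed_point <- function(params, delta = 0) {
  assert_lv_params(params)
  if (n_species(params) != 2) {
    stop_lv("lvdilute_invalid_params", "interior_fixed_point is defined for two species")
  }
  eff <- reparametrize_params(params, delta)
  a <- eff$alpha[1, 2]
  b <- eff$alpha[2, 1]
  det <- 1 - a * b
  if (abs(det) < 1e-12) {
    stop_lv("lvdilute_degenerate_boundary", "alpha_tilde_ij * alpha_tilde_ji = 1: nullclines are parallel")
  }
  nt <- c((1 - a) / det, (1 - b) / det)
  if (any(nt < 0)) {
    stop_lv("lvdilute_no_interior", sprintf(
      "no interior equilibrium: rescaled fixed point (%.4g, %.4g) has a negative component",
      nt[1], nt[2]))
  }
  scale <- 1 - delta / params$r
  n_orig <- nt * scale
  # Jacobian of dN_i/dt = N_i (r_i (1 - sum_j alpha_ij N_j) - delta) at N*;
  # at an interior equilibrium the bracket vanishes, leaving -diag(N r) alpha.
  J <- -diag(n_orig * params$r, 2) %*% params$alpha
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    list(abundances = setNames(n_orig, params$species),
         stable = max(Re(ev)) < 0, eigenvalues = ev, delta = delta),
    class = "lv_equilibrium"
  )
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  cat("Interior equilibrium (normalized abundances):\n")
  print(signif(x$abundances, 5))
  cat(sprintf("  %s (max Re eigenvalue = %.3g), delta = %.4g/day\n",
              if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues)), x$delta))
  invisible(x)
}

#' Mortality rate at which an effective coefficient crosses 1
#'
#' The qualitative pairwise outcome changes where an effective coefficient
#' equals 1.  Solving `reparametrize(alpha_ij, r_i, r_j, delta) = 1` for
#' `delta` gives
#' \deqn{\delta^* = \frac{1 - \alpha_{ij}}{1/r_i - \alpha_{ij}/r_j}.}
#' The crossing is only meaningful when `delta*` lies in
#' `[0, min(r_i, r_j))`; otherwise a classed `lvdilute_no_crossing` error is
#' raised.
#'
#' @inheritParams reparametrize
#' @return The critical mortality rate, 1/day.
#' @examples
#' critical_delta(1.5, r_i = 1, r_j = 0.5) # 0.25
#' @export
critical_delta <- function(alpha_ij, r_i, r_j) {
  if (alpha_ij == 1) return(0)
  den <- 1 / r_i - alpha_ij / r_j
  if (abs(den) < 1e-300) {
    stop_lv("lvdilute_no_crossing", "alpha_tilde is independent of delta for these parameters")
  }
  dstar <- (1 - alpha_ij) / den
  if (dstar < 0 || dstar >= min(r_i, r_j)) {
    stop_lv("lvdilute_no_crossing", sprintf(
      "alpha_tilde = 1 has no solution in [0, min r): delta* = %.4g with min(r) = %.4g",
      dstar, min(r_i, r_j)))
  }
  dstar
}

#' Phase table of effective coefficients and outcomes along a mortality grid
#'
#' Tabulates the effective coefficient pair and outcome label of a
#' two-species community over a grid of mortality rates or dilution factors.
#' Washout rows (where `delta` meets a growth rate) are labelled
#' `"WASHOUT_<species>"`; degenerate rows within the boundary tolerance of 1
#' are labelled `"BOUNDARY"`.
#'
#' @param params a two-species [lv_params] object.
#' @param delta_grid numeric vector of mortality rates (1/day); mutually
#'   exclusive with `df_grid`.
#' @param df_grid numeric vector of dilution factors, converted through
#'   [df_to_delta()] with `cycle_hours`.
#' @param cycle_hours cycle duration used to convert dilution factors.
#' @return A data frame with columns `delta`, `df`, `alpha_tilde_ij`,
#'   `alpha_tilde_ji`, `label`.
#' @export
phase_table <- function(params, delta_grid = NULL, df_grid = NULL,
                        cycle_hours = 24) {
  assert_lv_params(params)
  if (n_species(params) != 2) {
    stop_lv("lvdilute_invalid_params", "phase_table is defined for two species")
  }
  if (is.null(delta_grid) == is.null(df_grid)) {
    stop_lv("lvdilute_invalid_params", "supply exactly one of delta_grid or df_grid")
  }
  if (is.null(delta_grid)) delta_grid <- vapply(df_grid, df_to_delta, 0, cycle_hours = cycle_hours)
  df <- if (is.null(df_grid)) vapply(delta_grid, delta_to_df, 0, cycle_hours = cycle_hours) else df_grid
  r <- params$r
  rows <- lapply(seq_along(delta_grid), function(k) {
    d <- delta_grid[k]
    if (d >= min(r)) {
      who <- params$species[which(d >= r)]
      return(data.frame(delta = d, df = df[k], alpha_tilde_ij = NA_real_,
                        alpha_tilde_ji = NA_real_,
                        label = paste0("WASHOUT_", paste(who, collapse = "+"))))
    }
    at_ij <- unname(reparametrize(params$alpha[1, 2], r[[1]], r[[2]], d))
    at_ji <- unname(reparametrize(params$alpha[2, 1], r[[2]], r[[1]], d))
    lab <- tryCatch(classify_outcome(at_ij, at_ji)$label,
                    lvdilute_degenerate_boundary = function(e) "BOUNDARY")
    data.frame(delta = d, df = df[k], alpha_tilde_ij = at_ij,
               alpha_tilde_ji = at_ji, label = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
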