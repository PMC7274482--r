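#' Competition coefficient from an outcome-boundary dilution factor
#'
#' The qualitative pairwise outcome changes at the dilution factor where an
#' effective coefficient equals 1.  Inverting
#' `reparametrize(alpha_ij, r_i, r_j, delta*) = 1` at the boundary mortality
#' `delta* = df_to_delta(df)` gives
#' \deqn{\alpha_{ij} = \frac{1 - \delta^*/r_i}{1 - \delta^*/r_j}.}
#' This is the estimator used to read competition coefficients off a
#' bifurcation diagram.
#'
#' @param df dilution factor at which the outcome changes.
#' @param r_i,r_j growth rates (1/day) of the affected species i and
#'   competitor j.
#' @param cycle_hours cycle duration in hours.
#' @return The estimated `alpha_ij`.
#' @examples
#' estimate_alpha_from_boundary(delta_to_df(0.25), r_i = 1, r_j = 0.5) # 1.5
#' @export
estimate_alpha_from_boundary <- function(df, r_i, r_j, cycle_hours = 24) {
  dstar <- df_to_delta(df, cycle_hours)
  check_washout(c(r_i, r_j), dstar)
  (1 - dstar / r_i) / (1 - dstar / r_j)
}

# Coefficients that exceed 1 in each outcome region of a (fast, slow) pair.
# "fs" = effect on the fast grower, "sf" = effect on the slow grower.
region_above_one <- function(label, fast_is_i) {
  # labels are in (i, j) = (species1, species2) orientation
  switch(label,
    COEXISTENCE = character(0),
    BISTABILITY = c("fs", "sf"),
    EXCLUSION_I_WINS = if (fast_is_i) "sf" else "fs", # j suppressed
    EXCLUSION_J_WINS = if (fast_is_i) "fs" else "sf", # i suppressed
    NULL
  )
}

#' Fit a Lotka-Volterra community from a synthetic experiment bundle
#'
#' The package's central fitting routine, mirroring how the parameters of
#' the dilution experiment are estimated in practice: growth rates come from
#' time-to-threshold estimates on monoculture OD curves, and competition
#' coefficients come from the dilution factors at which the qualitative
#' pairwise outcome changes on the bifurcation grid.  Boundary DFs are
#' placed at the geometric midpoint of the bracketing grid points (the grid
#' is what a discrete experiment resolves), and each boundary is assigned to
#' the coefficient whose crossing direction explains the observed label
#' change.
#'
#' A label change is detected where the separatrix crosses the most extreme
#' initial fractions tested, not where a bistable window truly closes: near
#' the window edges the unstable branch of the discrete growth-dilution map
#' hugs the absorbing boundary.  Designs intended for coefficient recovery
#' should therefore include starting fractions close to 0 and 1; with only
#' central starting fractions the detected boundary systematically
#' underestimates the window width (see the package vignette).
#'
#' @param bundle an `lv_bundle` from [generate_bundle()] (two species).
#' @param use `"counts"` reads endpoint fractions from the plated colony
#'   counts (beta-posterior mean on the final sampled day); `"trajectories"`
#'   uses the simulated true fractions; `"auto"` prefers counts when
#'   present.
#' @param threshold threshold OD for growth-rate estimation.
#' @param cluster_tol endpoint clustering tolerance.
#' @param boundary_tol boundary tolerance for labeling endpoints; defaults
#'   to 0.1 for counts (49-colony platings cannot resolve fractions nearer
#'   the boundary) and 0.05 for trajectories.
#' @return An object of class `lv_fit` with components `r` (per-day
#'   estimates with SEM), `alpha` (estimated matrix, `NA` where no boundary
#'   informed the entry), `labels` (per-DF outcome labels), `boundaries`
#'   (data frame: bracketing DFs, midpoint, delta, coefficient), per-alpha
#'   `log_alpha_bound` (half-grid-step uncertainty propagated through the
#'   boundary estimator), and, when the bundle carries ground truth, a
#'   `recovery` data frame of relative errors.
#' @seealso [coef.lv_fit()], [predict.lv_fit()]
#' @export
lv_fit <- function(bundle, use = c("auto", "counts", "trajectories"),
                   threshold = 0.1, cluster_tol = 0.02, boundary_tol = NULL) {
  use <- match.arg(use)
  if (!inherits(bundle, "lv_bundle")) {
    stop_lv("lvdilute_invalid_params", "expected an 'lv_bundle'; see ?generate_bundle")
  }
  design <- bundle$design
  species <- bundle$species
  if (length(species) != 2) {
    stop_lv("lvdilute_invalid_params", "lv_fit estimates pairwise parameters (two species)")
  }
  if (use == "auto") use <- if (!is.null(bundle$counts)) "counts" else "trajectories"
  if (is.null(boundary_tol)) boundary_tol <- if (use == "counts") 0.1 else 0.05

  ## --- growth rates (1/hour on the OD time axis, converted to 1/day) ----
  oc <- bundle$od_curves
  rates <- lapply(species, function(sp) {
    cur <- oc[oc$species == sp, ]
    keys <- unique(cur[c("dilution", "replicate")])
    ests <- vapply(seq_len(nrow(keys)), function(k) {
      one <- cur[cur$dilution == keys$dilution[k] & cur$replicate == keys$replicate[k], ]
      estimate_growth_rate(one$time_h, one$od,
                           od0 = design$equalized_od * keys$dilution[k],
                           threshold = threshold)
    }, numeric(1))
    aggregate_growth_rates(ests, threshold)
  })
  names(rates) <- species
  r_day <- vapply(rates, `[[`, numeric(1), "estimate") * 24

  ## --- per-DF outcome labels on the constant-DF grid --------------------
  dfs <- sort(unique(bundle$trajectory_index$df[bundle$trajectory_index$kind == "constant"]))
  if (length(dfs) < 2) {
    stop_lv("lvdilute_uninformative", "need a constant-DF grid of at least two dilution factors")
  }
  endpoint <- function(df, init_id) {
    row <- which(bundle$trajectory_index$kind == "constant" &
                   bundle$trajectory_index$df == df &
                   bundle$trajectory_index$init_id == init_id)
    if (use == "trajectories") {
      return(final_fractions(bundle$trajectories[[row]])[1])
    }
    cond <- bundle$trajectory_index$condition[row]
    cc <- bundle$counts[bundle$counts$condition == cond, ]
    cc <- cc[cc$day == max(cc$day), ]
    a <- sum(cc$colonies[cc$species == species[1]])
    b <- sum(cc$colonies[cc$species == species[2]])
    fraction_estimate(a, b)
  }
  init_ids <- sort(unique(bundle$trajectory_index$init_id))
  labels <- vapply(dfs, function(df) {
    eps <- vapply(init_ids, function(i) endpoint(df, i), numeric(1))
    classify_endpoints(eps, cluster_tol, boundary_tol)$label
  }, character(1))

  # drop grid points whose endpoint pattern is uninterpretable (typically
  # conditions that had not equilibrated); boundaries are read between the
  # nearest interpretable neighbours
  ok <- labels %in% c("COEXISTENCE", "BISTABILITY",
                      "EXCLUSION_I_WINS", "EXCLUSION_J_WINS")
  dfs_ok <- dfs[ok]
  labels_ok <- labels[ok]
  changes <- which(labels_ok[-1] != labels_ok[-length(labels_ok)])
  if (!length(changes)) {
    stop_lv("lvdilute_uninformative", sprintf(
      "uninformative design: a single outcome (%s) was observed at every dilution factor, so no boundary constrains alpha",
      labels[1]))
  }

  ## --- boundaries -> coefficients ---------------------------------------
  fast_is_i <- r_day[1] >= r_day[2]
  fast <- if (fast_is_i) 1 else 2
  slow <- 3 - fast
  coef_idx <- list(fs = c(fast, slow), sf = c(slow, fast)) # (affected i, agent j)
  cyc <- design$cycle_hours
  alpha_hat <- matrix(NA_real_, 2, 2, dimnames = list(species, species))
  diag(alpha_hat) <- 1
  bound <- matrix(NA_real_, 2, 2, dimnames = list(species, species))
  brows <- list()
  for (ch in changes) {
    left <- region_above_one(labels_ok[ch], fast_is_i)
    right <- region_above_one(labels_ok[ch + 1], fast_is_i)
    crossed <- union(setdiff(left, right), setdiff(right, left))
    df_mid <- sqrt(dfs_ok[ch] * dfs_ok[ch + 1])
    dstar <- df_to_delta(df_mid, cyc)
    half_step <- diff(log(c(dfs_ok[ch], dfs_ok[ch + 1]))) / 2 / (cyc / 24)
    for (cf in crossed) {
      i <- coef_idx[[cf]][1]; j <- coef_idx[[cf]][2]
      a_hat <- tryCatch(
        estimate_alpha_from_boundary(df_mid, r_day[i], r_day[j], cyc),
        lvdilute_washout = function(e) NA_real_)
      if (is.na(a_hat)) next
      alpha_hat[i, j] <- a_hat
      # |d log(alpha_hat) / d delta| * half grid step in delta
      bound[i, j] <- abs(1 / (r_day[j] - dstar) - 1 / (r_day[i] - dstar)) * half_step
      brows[[length(brows) + 1]] <- data.frame(
        df_lo = dfs_ok[ch], df_hi = dfs_ok[ch + 1], df_mid = df_mid, delta = dstar,
        affected = species[i], agent = species[j], alpha = a_hat,
        log_alpha_bound = bound[i, j],
        label_change = paste(labels_ok[ch], "->", labels_ok[ch + 1]))
    }
  }
  boundaries <- if (length(brows)) do.call(rbind, brows) else NULL
  if (is.null(boundaries)) {
    stop_lv("lvdilute_uninformative",
            "no interpretable outcome boundary found on the dilution grid")
  }

  fit <- list(species = species, r = r_day, rates = rates,
              alpha = alpha_hat, log_alpha_bound = bound, labels = setNames(labels, dfs),
              boundaries = boundaries, use = use, design = design)
  if (!is.null(bundle$params)) {
    truth <- bundle$params
    rec <- data.frame(
      quantity = c(paste0("r_", species),
                   paste0("alpha_", species[1], "_", species[2]),
                   paste0("alpha_", species[2], "_", species[1])),
      truth = c(truth$r, truth$alpha[1, 2], truth$alpha[2, 1]),
      estimate = c(r_day, alpha_hat[1, 2], alpha_hat[2, 1]))
    rec$rel_error <- abs(rec$estimate - rec$truth) / rec$truth
    fit$recovery <- rec
  }
  structure(fit, class = "lv_fit")
}

#' @export
print.lv_fit <- function(x, ...) {
  cat("Lotka-Volterra fit from growth-dilution data (", x$use, ")\n", sep = "")
  cat("  growth rates (1/day):\n")
  print(round(x$r, 4))
  cat("  competition coefficients (row = affected species):\n")
  print(round(x$alpha, 4))
  cat(sprintf("  %d outcome boundar%s located on the DF grid\n",
              nrow(x$boundaries), if (nrow(x$boundaries) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
summary.lv_fit <- function(object, ...) {
  cat("Outcome labels along the constant-DF grid:\n")
  print(object$labels)
  cat("\nBoundaries:\n")
  print(object$boundaries, row.names = FALSE)
  if (!is.null(object$recovery)) {
    cat("\nRecovery vs ground truth:\n")
    print(object$recovery, row.names = FALSE)
  }
  invisible(object)
}

#' Extract fitted parameters
#'
#' @param object an `lv_fit`.
#' @param ... unused.
#' @return A list with `r` (1/day) and `alpha`.
#' @export
coef.lv_fit <- function(object, ...) {
  list(r = object$r, alpha = object$alpha)
}

#' Predict the competitive outcome at a dilution factor
#'
#' Uses the fitted parameters to reparametrize the pair at the mortality
#' rate matching `df` and classify the outcome analytically.
#'
#' @param object an `lv_fit` with both off-diagonal coefficients estimated.
#' @param df dilution factor(s) at which to predict.
#' @param cycle_hours cycle duration in hours.
#' @param ... unused.
#' @return A character vector of outcome labels.
#' @export
predict.lv_fit <- function(object, df, cycle_hours = 24, ...) {
  if (any(is.na(object$alpha))) {
    stop_lv("lvdilute_uninformative", "both coefficients must be estimated to predict outcomes")
  }
  p <- lv_params(r = object$r, alpha = object$alpha, species = object$species)
  phase_table(p, df_grid = df, cycle_hours = cycle_hours)$label
}
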