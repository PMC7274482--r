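#' Design of a synthetic growth-dilution experiment
#'
#' Describes the layout the synthetic-data generator emulates: which
#' constant dilution factors and fluctuating schedules are run, from which
#' initial fractions and for how many days; how deeply each condition is
#' plated; and how monoculture OD curves are sampled.  Defaults mirror a
#' plate-based serial-dilution coculture study: 5 starting fractions, a
#' decade-spaced DF grid, 7 daily transfers, platings averaging 49 colonies,
#' and 15-minute OD sampling over 40 h from inocula spread over decades of
#' starting density.
#'
#' @param n_species number of species (2 or 3).
#' @param initial_fractions for pairs, a numeric vector of starting
#'   fractions of species 1; for trios, a matrix with one composition per
#'   row.
#' @param dfs constant dilution factors to run.
#' @param schedules optional list of [lv_schedule] objects (fluctuating
#'   conditions).
#' @param days number of growth-dilution cycles.
#' @param platings plating replicates per condition per sampled day.
#' @param target_colonies mean colonies per plating (Poisson mean).
#' @param od_dilutions inoculum dilution factors for the OD curves,
#'   as fractions of the equalized OD.
#' @param od_replicates OD curve replicates per dilution.
#' @param od_interval_min OD sampling interval in minutes.
#' @param od_duration_h OD curve duration in hours.
#' @param od_noise_sd additive Gaussian OD noise SD (clipped at 0).
#' @param lag_h dead-time lag before growth starts, in hours (scalar or per
#'   species).
#' @param equalized_od OD to which monocultures are equalized before
#'   inoculation; defaults to the smallest carrying capacity at generation
#'   time.
#' @param cycle_hours growth-cycle duration in hours.
#' @return A validated list of class `lv_design`.
#' @export
experiment_design <- function(n_species = 2,
                              initial_fractions = c(0.05, 0.25, 0.5, 0.75, 0.95),
                              dfs = 10^(1:6), schedules = NULL, days = 7,
                              platings = 1, target_colonies = 49,
                              od_dilutions = 10^-(7:3), od_replicates = 3,
                              od_interval_min = 15, od_duration_h = 40,
                              od_noise_sd = 0, lag_h = 0,
                              equalized_od = NULL, cycle_hours = 24) {
  if (!n_species %in% 2:3) stop_lv("lvdilute_invalid_design", "n_species must be 2 or 3")
  if (is.matrix(initial_fractions)) {
    if (ncol(initial_fractions) != n_species ||
        any(abs(rowSums(initial_fractions) - 1) > 1e-8) ||
        any(initial_fractions < 0)) {
      stop_lv("lvdilute_invalid_design", "initial composition rows must be non-negative and sum to 1")
    }
  } else {
    if (n_species != 2) stop_lv("lvdilute_invalid_design", "trio designs need a composition matrix")
    if (any(initial_fractions < 0 | initial_fractions > 1)) {
      stop_lv("lvdilute_invalid_design", "initial fractions must lie in [0, 1]")
    }
    initial_fractions <- cbind(initial_fractions, 1 - initial_fractions)
  }
  if (days < 0) stop_lv("lvdilute_invalid_design", "days must be >= 0")
  if (platings < 1 || target_colonies <= 0) {
    stop_lv("lvdilute_invalid_design", "platings >= 1 and target_colonies > 0 required")
  }
  if (!is.null(dfs)) dfs <- normalize_df(dfs)
  if (!is.null(schedules)) {
    schedules <- lapply(schedules, as_schedule, cycle_hours = cycle_hours)
  }
  structure(list(n_species = n_species, initial_fractions = initial_fractions,
                 dfs = dfs, schedules = schedules, days = days,
                 platings = platings, target_colonies = target_colonies,
                 od_dilutions = od_dilutions, od_replicates = od_replicates,
                 od_interval_min = od_interval_min,
                 od_duration_h = od_duration_h, od_noise_sd = od_noise_sd,
                 lag_h = lag_h, equalized_od = equalized_od,
                 cycle_hours = cycle_hours),
            class = "lv_design")
}

#' Sample community parameters in a requested outcome regime
#'
#' Draws growth rates log-uniformly (default 0.2-1.5 per hour, converted to
#' the canonical 1/day) and competition coefficients placing the pair in
#' the requested region of the effective-coefficient phase plane, verified
#' by [classify_outcome()].  Regimes:
#'
#' * `"coexist"`, `"bistable"`, `"dominance"`: both/neither/exactly one
#'   coefficient above 1 at zero mortality.
#' * `"random"`: unconstrained draw away from the degenerate boundary.
#' * `"switch_bistable"`, `"switch_coexist"`: a pair whose outcome switches
#'   from slow-grower dominance at `df_low` to fast-grower dominance at
#'   `df_high`, passing through bistability (resp. coexistence) at the
#'   geometric-mean DF, with margin `margin` on every effective coefficient
#'   at the three probed mortalities.
#'
#' @param n_species 1, 2 or 3 (structured regimes need 2).
#' @param regime outcome regime, see above.
#' @param seed optional RNG seed (fixed seed gives identical parameters).
#' @param r_range_hr growth-rate range, 1/hour.
#' @param df_low,df_high DF window for the switching regimes.
#' @param margin required margin `|alpha_tilde - 1|` for the switching
#'   regimes.
#' @param cycle_hours cycle duration used to convert the DF window.
#' @param max_tries rejection-sampling bound; exceeding it raises a classed
#'   `lvdilute_regime_infeasible` error.
#' @param K_range carrying-capacity range (OD units), drawn uniformly.
#' @return An [lv_params] object (attribute `"regime"` records the request).
#' @export
sample_params <- function(n_species = 2,
                          regime = c("coexist", "bistable", "dominance",
                                     "random", "switch_bistable",
                                     "switch_coexist"),
                          seed = NULL, r_range_hr = c(0.2, 1.5),
                          df_low = 10, df_high = 1e4, margin = 0.05,
                          cycle_hours = 24, max_tries = 5000,
                          K_range = c(1.0, 1.6)) {
  regime <- match.arg(regime)
  if (!n_species %in% 1:3) stop_lv("lvdilute_invalid_design", "n_species must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  draw_r <- function(n) exp(runif(n, log(r_range_hr[1]), log(r_range_hr[2]))) * 24
  draw_K <- function(n) runif(n, K_range[1], K_range[2])

  if (n_species == 1) {
    return(structure(lv_params(r = draw_r(1), alpha = matrix(1, 1, 1),
                               K = draw_K(1)), regime = regime))
  }
  if (n_species == 3 || regime == "random") {
    for (try in seq_len(max_tries)) {
      r <- draw_r(n_species)
      a <- matrix(runif(n_species^2, 0.3, 2), n_species)
      diag(a) <- 1
      if (all(abs(a[row(a) != col(a)] - 1) > margin)) {
        return(structure(lv_params(r = r, alpha = a, K = draw_K(n_species)),
                         regime = regime))
      }
    }
    stop_lv("lvdilute_regime_infeasible",
            sprintf("no draw satisfied regime '%s' in %d tries", regime, max_tries))
  }

  d_lo <- df_to_delta(df_low, cycle_hours)
  d_hi <- df_to_delta(df_high, cycle_hours)
  d_mid <- df_to_delta(sqrt(df_low * df_high), cycle_hours)
  target_mid <- if (regime == "switch_bistable") "BISTABILITY" else "COEXISTENCE"

  for (try in seq_len(max_tries)) {
    r <- draw_r(2)
    a12 <- switch(regime,
      coexist = runif(1, 0.3, 1 - 2 * margin),
      bistable = runif(1, 1 + 2 * margin, 2),
      dominance = runif(1, 1 + 2 * margin, 2),
      switch_bistable = ,
      switch_coexist = runif(1, 1 + 2 * margin, 2.2))
    a21 <- switch(regime,
      coexist = runif(1, 0.3, 1 - 2 * margin),
      bistable = runif(1, 1 + 2 * margin, 2),
      dominance = runif(1, 0.3, 1 - 2 * margin),
      switch_bistable = ,
      switch_coexist = runif(1, 0.35, 1 - 2 * margin))
    a <- matrix(c(1, a12, a21, 1), 2, byrow = TRUE)
    if (regime %in% c("coexist", "bistable", "dominance")) {
      lab <- classify_outcome(a12, a21)$label
      want <- switch(regime, coexist = "COEXISTENCE", bistable = "BISTABILITY",
                     dominance = "EXCLUSION_J_WINS")
      if (lab == want) {
        return(structure(lv_params(r = r, alpha = a, K = draw_K(2)),
                         regime = regime))
      }
      next
    }
    # switching regimes: orient species 1 = fast, species 2 = slow, require
    # slow wins at df_low, target label at the mid DF, fast wins at df_high,
    # with margin on every effective coefficient and no washout.
    r <- sort(r, decreasing = TRUE)
    if (r[1] / r[2] < 1.25) next
    if (d_hi >= 0.9 * r[2]) next
    ok <- TRUE
    for (dd in c(d_lo, d_mid, d_hi)) {
      at12 <- reparametrize(a12, r[1], r[2], dd)
      at21 <- reparametrize(a21, r[2], r[1], dd)
      if (min(abs(at12 - 1), abs(at21 - 1)) <= margin) { ok <- FALSE; break }
      lab <- classify_outcome(at12, at21)$label
      want <- if (dd == d_lo) "EXCLUSION_J_WINS"
              else if (dd == d_hi) "EXCLUSION_I_WINS"
              else target_mid
      if (lab != want) { ok <- FALSE; break }
    }
    if (!ok) next
    # the switching regimes are defined by the outcomes of the serial
    # growth-dilution experiment itself; the discrete protocol shifts
    # outcome windows relative to the continuous phase diagram, so verify
    # the three probed dilution factors by simulation as well
    cand <- lv_params(r = r, alpha = a, K = draw_K(2))
    cfg <- sim_config(max_cycles = 150, conv_eps = 1e-6)
    want_seq <- c("EXCLUSION_J_WINS", target_mid, "EXCLUSION_I_WINS")
    sims <- lapply(c(df_low, sqrt(df_low * df_high), df_high), function(df)
      classify_by_simulation(cand, dilution_schedule(df, cycle_hours),
                             inits = c(0.05, 0.5, 0.95), config = cfg))
    got <- vapply(sims, `[[`, character(1), "label")
    if (!identical(got, want_seq)) next
    # marginal coexistence (interior state close to an absorbing boundary)
    # is fragile under fluctuating mortality -- exactly the regime where
    # time-averaging is expected to break down -- so the coexisting regime
    # requires an equitable interior state at the mid dilution factor
    if (regime == "switch_coexist") {
      mid_frac <- sims[[2]]$stable_states[1]
      if (mid_frac < 0.2 || mid_frac > 0.8) next
    }
    return(structure(cand, regime = regime))
  }
  stop_lv("lvdilute_regime_infeasible",
          sprintf("no draw satisfied regime '%s' in %d tries", regime, max_tries))
}

#' Generate monoculture OD growth curves
#'
#' Logistic growth in OD units from a low inoculum: each species grows at
#' its maximum rate toward its carrying capacity, optionally after a
#' dead-time lag, sampled on the design's grid with additive Gaussian noise
#' clipped at zero.  Inocula are the equalized OD diluted by each of the
#' design's dilution factors, spreading starting densities over decades.
#'
#' @param params an [lv_params] with carrying capacities `K` (OD units);
#'   missing `K` defaults to 0.5.
#' @param design an [experiment_design()].
#' @return A data frame (`species`, `dilution`, `replicate`, `time_h`,
#'   `od`) with attribute `"truth"` recording the generating rates (1/hour),
#'   `K`, lag and equalized OD.
#' @export
generate_od_curves <- function(params, design) {
  assert_lv_params(params)
  K <- params$K %||% setNames(rep(1.2, n_species(params)), params$species)
  eq_od <- design$equalized_od %||% min(K)
  r_hr <- params$r / 24
  lag <- rep(design$lag_h, length.out = n_species(params))
  tgrid <- seq(0, design$od_duration_h, by = design$od_interval_min / 60)
  rows <- list()
  for (s in seq_along(params$species)) {
    for (dil in design$od_dilutions) {
      od0 <- eq_od * dil
      for (rep_i in seq_len(design$od_replicates)) {
        te <- pmax(tgrid - lag[s], 0)
        g <- exp(r_hr[s] * te)
        od <- K[s] * od0 * g / (K[s] + od0 * (g - 1))
        if (design$od_noise_sd > 0) {
          od <- pmax(od + rnorm(length(od), 0, design$od_noise_sd), 0)
        }
        rows[[length(rows) + 1]] <- data.frame(
          species = params$species[s], dilution = dil, replicate = rep_i,
          time_h = tgrid, od = od)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(r_hr = r_hr, K = K, lag_h = lag,
                             equalized_od = eq_od)
  out
}

#' Generate colony-count observations from a trajectory
#'
#' Emulates daily platings: on each sampled day the total colony count is
#' Poisson with the design's target mean and the split across species is
#' multinomial on the true fractions of that day (day 0 uses the initial
#' mix).  The two-species case reduces to binomial sampling.
#'
#' @param trajectory an `lv_trajectory`.
#' @param design an [experiment_design()].
#' @param days days to sample (default 0 through the trajectory length,
#'   capped at `design$days`).
#' @param condition condition label recorded in the table.
#' @return A data frame (`condition`, `day`, `replicate`, `species`,
#'   `colonies`).  Platings with zero total colonies are retained (they are
#'   uninformative but real).
#' @export
generate_count_tables <- function(trajectory, design, days = NULL,
                                  condition = "cond1") {
  species <- trajectory$species
  days <- days %||% 0:min(design$days, length(trajectory$cycle))
  rows <- list()
  for (d in days) {
    fr <- if (d == 0) trajectory$initial_fractions else trajectory$fraction[d, ]
    if (any(!is.finite(fr))) fr <- rep(0, length(fr))
    for (p in seq_len(design$platings)) {
      total <- rpois(1, design$target_colonies)
      counts <- if (total > 0 && sum(fr) > 0) {
        as.vector(rmultinom(1, total, fr))
      } else {
        rep(0L, length(species))
      }
      rows[[length(rows) + 1]] <- data.frame(
        condition = condition, day = d, replicate = p, species = species,
        colonies = counts)
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic experiment bundle
#'
#' Composes the generator end to end: samples (or accepts) ground-truth
#' parameters, simulates every condition in the design (constant DFs and
#' fluctuating schedules, honoring the day-0 pre-dilution convention with a
#' first-cycle cap at DF 1e5 to avoid wiping the inoculum), and draws OD
#' curves and colony-count tables from the true states.  Everything is
#' reproducible from `(design, params, seed)`.
#'
#' @param design an [experiment_design()].
#' @param params optional [lv_params] ground truth; sampled via
#'   [sample_params()] (regime `regime`) when omitted.
#' @param seed RNG seed; recorded in the bundle.
#' @param regime regime for [sample_params()] when `params` is missing.
#' @param config simulator settings; defaults to running exactly
#'   `design$days` cycles.
#' @return An object of class `lv_bundle`: list with `design`, `params`
#'   (ground truth), `species`, `trajectories`, `trajectory_index`,
#'   `od_curves`, `counts`, `seed`.
#' @export
generate_bundle <- function(design, params = NULL, seed = 1,
                            regime = "switch_bistable", config = NULL) {
  if (!inherits(design, "lv_design")) {
    stop_lv("lvdilute_invalid_design", "expected an 'lv_design'; see ?experiment_design")
  }
  set.seed(seed)
  if (is.null(params)) {
    params <- sample_params(design$n_species, regime, cycle_hours = design$cycle_hours)
  }
  assert_lv_params(params)
  design <- within_design_eq(design, params)
  config <- config %||% sim_config(max_cycles = max(design$days, 1), conv_eps = 0)

  conds <- list()
  if (!is.null(design$dfs)) {
    for (df in design$dfs) {
      conds[[length(conds) + 1]] <- list(kind = "constant", df = df,
                                         schedule = dilution_schedule(df, design$cycle_hours))
    }
  }
  if (!is.null(design$schedules)) {
    for (s in seq_along(design$schedules)) {
      conds[[length(conds) + 1]] <- list(kind = "schedule", df = NA_real_,
                                         schedule = design$schedules[[s]],
                                         schedule_id = s)
    }
  }
  if (!length(conds)) stop_lv("lvdilute_invalid_design", "design has no conditions")

  trajectories <- list()
  idx <- list()
  counts <- list()
  for (ci in seq_along(conds)) {
    cn <- conds[[ci]]
    for (init_id in seq_len(nrow(design$initial_fractions))) {
      fr0 <- design$initial_fractions[init_id, ]
      label <- if (cn$kind == "constant") {
        sprintf("df%g_init%d", cn$df, init_id)
      } else {
        sprintf("sched%d_init%d", cn$schedule_id, init_id)
      }
      first_df <- min(cn$schedule$dfs[1], 1e5) # day-0 stochastic-extinction guard
      tr <- run_schedule(params, cn$schedule, fr0, total_density = 1,
                         config = config, first_df = first_df)
      trajectories[[length(trajectories) + 1]] <- tr
      idx[[length(idx) + 1]] <- data.frame(
        kind = cn$kind, df = cn$df,
        schedule_id = if (cn$kind == "schedule") cn$schedule_id else NA_integer_,
        init_id = init_id, condition = label)
      counts[[length(counts) + 1]] <- generate_count_tables(tr, design,
                                                            condition = label)
    }
  }
  structure(
    list(design = design, params = params, species = params$species,
         trajectories = trajectories, trajectory_index = do.call(rbind, idx),
         od_curves = generate_od_curves(params, design),
         counts = do.call(rbind, counts), seed = seed),
    class = "lv_bundle"
  )
}

# resolve the design's equalized OD against the sampled K before generating
within_design_eq <- function(design, params) {
  if (is.null(design$equalized_od)) {
    K <- params$K %||% rep(1.2, n_species(params))
    design$equalized_od <- min(K)
  }
  design
}

#' @export
print.lv_bundle <- function(x, ...) {
  cat(sprintf("Synthetic experiment bundle (seed %d): %d species, %d trajectories\n",
              x$seed, length(x$species), length(x$trajectories)))
  cat(sprintf("  %d count rows, %d OD samples\n", nrow(x$counts), nrow(x$od_curves)))
  cat("  ground truth:\n")
  print(x$params)
  invisible(x)
}
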