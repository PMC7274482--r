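#' Simulation configuration
#'
#' Numerical and stochastic settings for the growth-dilution simulator.
#'
#' @param rtol,atol relative/absolute integration tolerances passed to
#'   [deSolve::ode()].
#' @param extinction_threshold normalized abundance below which a species is
#'   set to zero after dilution (a deterministic stand-in for finite
#'   population size).  Set to 0 to disable.
#' @param max_cycles maximum number of growth-dilution cycles.
#' @param conv_eps convergence tolerance: the run stops early once the
#'   end-of-cycle fractions change by less than `conv_eps` across one full
#'   schedule period, for `conv_window` consecutive periods.  Set to 0 to
#'   always run `max_cycles`.
#' @param conv_window number of consecutive converged periods required.
#' @param stochastic if `TRUE`, dilution draws surviving cell counts
#'   binomially instead of dividing deterministically.
#' @param cells_per_unit number of cells corresponding to one unit of
#'   normalized abundance (required in stochastic mode).
#' @return A list of class `lv_config`.
#' @export
sim_config <- function(rtol = 1e-8, atol = 1e-12, extinction_threshold = 1e-8,
                       max_cycles = 200, conv_eps = 1e-6, conv_window = 3,
                       stochastic = FALSE, cells_per_unit = NULL) {
  if (rtol <= 0 || atol <= 0) stop_lv("lvdilute_invalid_config", "tolerances must be positive")
  if (extinction_threshold < 0 || extinction_threshold >= 1) {
    stop_lv("lvdilute_invalid_config", "extinction_threshold must be in [0, 1)")
  }
  if (max_cycles < 1) stop_lv("lvdilute_invalid_config", "max_cycles must be >= 1")
  if (stochastic && is.null(cells_per_unit)) {
    stop_lv("lvdilute_invalid_config", "stochastic mode needs cells_per_unit")
  }
  structure(list(rtol = rtol, atol = atol,
                 extinction_threshold = extinction_threshold,
                 max_cycles = max_cycles, conv_eps = conv_eps,
                 conv_window = conv_window, stochastic = stochastic,
                 cells_per_unit = cells_per_unit),
            class = "lv_config")
}

LV_NMAX <- 8

pack_parms <- function(params, delta, r = NULL, alpha = NULL) {
  r <- r %||% params$r
  alpha <- alpha %||% params$alpha
  n <- length(r)
  if (n > LV_NMAX) {
    stop_lv("lvdilute_invalid_params", sprintf("at most %d species supported", LV_NMAX))
  }
  rp <- numeric(LV_NMAX); rp[seq_len(n)] <- r
  A <- matrix(0, LV_NMAX, LV_NMAX); A[seq_len(n), seq_len(n)] <- alpha
  c(n, delta, rp, as.vector(t(A)))
}

lv_ode <- function(y, t_days, params, delta, config) {
  out <- tryCatch(
    deSolve::ode(y = as.numeric(y), times = c(0, t_days), func = "lv_deriv",
                 parms = pack_parms(params, delta), dllname = "lvdilute",
                 initfunc = "lv_init", rtol = config$rtol, atol = config$atol),
    error = function(e) stop_lv("lvdilute_integration_failure", conditionMessage(e))
  )
  pmax(as.numeric(out[nrow(out), -1]), 0)
}

# Plain-R right-hand side, kept as an independent route for cross-checking
# the compiled model in tests.
lv_rhs_r <- function(t, y, parms) {
  with(parms, list(y * (r * (1 - as.numeric(alpha %*% y)) - delta)))
}

#' Integrate the Lotka-Volterra model with continuous mortality
#'
#' Theory-check mode: integrates the community with the mortality rate
#' applied continuously rather than as discrete dilutions.  Used for
#' discrete-vs-continuous consistency checks and as a brute-force oracle for
#' outcome classification.
#'
#' @param params an [lv_params] object.
#' @param state0 initial normalized abundances.
#' @param t_days total integration time in days (scalar) or a vector of
#'   output times.
#' @param delta continuous mortality rate, 1/day.
#' @param config an [sim_config()] (tolerances only).
#' @return A matrix of abundances with one row per output time (attribute
#'   `"times"` carries the time grid); if `t_days` is scalar, the final
#'   state vector.
#' @export
integrate_lv <- function(params, state0, t_days, delta = 0,
                         config = sim_config()) {
  assert_lv_params(params)
  scalar <- length(t_days) == 1
  times <- if (scalar) c(0, t_days) else t_days
  out <- tryCatch(
    deSolve::ode(y = as.numeric(state0), times = times, func = "lv_deriv",
                 parms = pack_parms(params, delta), dllname = "lvdilute",
                 initfunc = "lv_init", rtol = config$rtol, atol = config$atol,
                 maxsteps = 1e5),
    error = function(e) stop_lv("lvdilute_integration_failure", conditionMessage(e))
  )
  if (scalar) return(pmax(as.numeric(out[nrow(out), -1]), 0))
  m <- pmax(unname(out[, -1, drop = FALSE]), 0)
  colnames(m) <- params$species
  attr(m, "times") <- out[, 1]
  m
}

#' Grow the community for one cycle
#'
#' Integrates the mortality-free Lotka-Volterra system for one growth phase
#' of `cycle_hours`.  Species at exactly zero stay at zero (no spontaneous
#' generation).
#'
#' @param abundances non-negative normalized abundances.
#' @param params an [lv_params] object.
#' @param cycle_hours growth duration in hours.
#' @param config an [sim_config()].
#' @return Abundances after growth.
#' @export
grow_cycle <- function(abundances, params, cycle_hours = 24,
                       config = sim_config()) {
  assert_lv_params(params)
  if (any(abundances < 0)) stop_lv("lvdilute_invalid_state", "abundances must be >= 0")
  if (all(abundances == 0)) return(abundances)
  lv_ode(abundances, cycle_hours / 24, params, delta = 0, config = config)
}

#' Dilute the community at a serial transfer
#'
#' Divides each abundance by the fold dilution.  In the default
#' deterministic mode any result below `config$extinction_threshold` is set
#' to zero; in stochastic mode the number of surviving cells is drawn
#' binomially with success probability `1/df` given
#' `config$cells_per_unit` cells per unit abundance.
#'
#' @param abundances non-negative normalized abundances.
#' @param df fold dilution (>= 1).
#' @param config an [sim_config()].
#' @return Abundances after dilution.
#' @export
apply_dilution <- function(abundances, df, config = sim_config()) {
  df <- normalize_df(df)
  if (config$stochastic) {
    cells <- round(abundances * config$cells_per_unit)
    surv <- rbinom(length(cells), size = cells, prob = min(1, 1 / df))
    return(surv / config$cells_per_unit)
  }
  out <- abundances / df
  out[out < config$extinction_threshold] <- 0
  out
}

#' Run a growth-dilution experiment
#'
#' Simulates the serial-transfer experiment: each cycle the culture is
#' diluted by that cycle's dilution factor and then grows for
#' `cycle_hours`.  Following the experimental protocol, the initial mix is
#' pre-diluted by the first cycle's DF (day-0 convention); `first_df`
#' overrides the dilution applied on the first cycle only, mirroring the
#' practice of starting very high-DF cultures at a milder dilution to avoid
#' stochastic extinction on day 0.
#'
#' The schedule repeats cyclically up to `config$max_cycles`, stopping early
#' when end-of-cycle fractions are stationary across schedule periods (see
#' [sim_config()]).  Non-convergence is reported via the `converged` flag,
#' not an error.
#'
#' @param params an [lv_params] object.
#' @param schedule an [lv_schedule], or a numeric vector of dilution factors
#'   (a single number means a constant environment).
#' @param initial_fractions species fractions at day 0 (must sum to 1).
#' @param total_density total normalized density of the initial mix before
#'   the day-0 dilution (default 1, i.e. a saturated mixed culture).
#' @param config an [sim_config()].
#' @param first_df optional override of the dilution factor applied on the
#'   first cycle.
#' @return An object of class `lv_trajectory`: list with `cycle`,
#'   `abundance` (cycles x species matrix, end of each growth phase),
#'   `fraction`, `df_applied`, `converged`, `species`,
#'   `initial_fractions`, `schedule`.
#' @examples
#' p <- lv_params(r = c(12, 7), alpha = matrix(c(1, .6, .8, 1), 2, byrow = TRUE))
#' tr <- run_schedule(p, 100, initial_fractions = c(0.5, 0.5))
#' tail(as.data.frame(tr))
#' @export
run_schedule <- function(params, schedule, initial_fractions,
                         total_density = 1, config = sim_config(),
                         first_df = NULL) {
  assert_lv_params(params)
  schedule <- as_schedule(schedule)
  n <- n_species(params)
  if (length(initial_fractions) != n || any(initial_fractions < 0)) {
    stop_lv("lvdilute_invalid_state", "initial_fractions must be non-negative, one per species")
  }
  if (abs(sum(initial_fractions) - 1) > 1e-8) {
    stop_lv("lvdilute_invalid_state", "initial_fractions must sum to 1")
  }
  if (total_density <= 0) stop_lv("lvdilute_invalid_state", "total_density must be positive")

  dfs <- schedule$dfs
  L <- length(dfs)
  mc <- config$max_cycles
  ab <- matrix(NA_real_, mc, n)
  fr <- matrix(NA_real_, mc, n)
  df_applied <- numeric(mc)
  state <- initial_fractions * total_density
  converged <- FALSE
  ncyc <- mc
  for (cycle in seq_len(mc)) {
    df <- dfs[(cycle - 1) %% L + 1]
    if (cycle == 1 && !is.null(first_df)) df <- normalize_df(first_df)
    state <- apply_dilution(state, df, config)
    state <- grow_cycle(state, params, schedule$cycle_hours, config)
    ab[cycle, ] <- state
    tot <- sum(state)
    fr[cycle, ] <- if (tot > 0) state / tot else rep(NA_real_, n)
    df_applied[cycle] <- df
    if (config$conv_eps > 0 && cycle >= L * (config$conv_window + 1)) {
      lags <- cycle - L * seq_len(config$conv_window)
      heads <- c(cycle, lags[-config$conv_window])
      diffs <- abs(fr[heads, , drop = FALSE] - fr[lags, , drop = FALSE])
      # fractions stationary across schedule periods AND total abundance
      # stationary (relative), so a washing-out monoculture is not declared
      # converged while it still decays
      tot_h <- rowSums(ab[heads, , drop = FALSE])
      tot_l <- rowSums(ab[lags, , drop = FALSE])
      tot_rel <- abs(tot_h - tot_l) / pmax(tot_h, tot_l, 1e-300)
      if (all(is.finite(diffs)) && max(diffs) < config$conv_eps &&
          max(tot_rel) < max(config$conv_eps, 1e-8) * 100) {
        converged <- TRUE
        ncyc <- cycle
        break
      }
    }
  }
  keep <- seq_len(ncyc)
  colnames(ab) <- colnames(fr) <- params$species
  structure(
    list(cycle = keep, abundance = ab[keep, , drop = FALSE],
         fraction = fr[keep, , drop = FALSE], df_applied = df_applied[keep],
         converged = converged, species = params$species,
         initial_fractions = setNames(initial_fractions, params$species),
         schedule = schedule),
    class = "lv_trajectory"
  )
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat(sprintf("Growth-dilution trajectory: %d cycle(s), %d species (%s)\n",
              length(x$cycle), length(x$species),
              if (x$converged) "converged" else "not converged"))
  cat("  final fractions:\n")
  print(signif(final_fractions(x), 4))
  invisible(x)
}

#' @export
as.data.frame.lv_trajectory <- function(x, ...) {
  n <- length(x$species)
  m <- length(x$cycle)
  data.frame(
    cycle = rep(x$cycle, each = n),
    species = rep(x$species, times = m),
    abundance = as.vector(t(x$abundance)),
    fraction = as.vector(t(x$fraction)),
    df_applied = rep(x$df_applied, each = n)
  )
}

#' @export
plot.lv_trajectory <- function(x, ...) {
  graphics::matplot(x$cycle, x$fraction, type = "b", pch = 16, lty = 1,
                    xlab = "cycle (day)", ylab = "fraction", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = x$species, col = seq_along(x$species),
                   pch = 16, bty = "n")
  invisible(x)
}

final_fractions <- function(traj) traj$fraction[nrow(traj$fraction), ]
final_abundances <- function(traj) traj$abundance[nrow(traj$abundance), ]

#' Simulate trajectories from community parameters
#'
#' `simulate` method for [lv_params]: runs the growth-dilution experiment
#' `nsim` times.  Deterministic configurations return identical replicates;
#' with `config$stochastic = TRUE` dilution survival is resampled each run.
#'
#' @param object an [lv_params] object.
#' @param nsim number of replicate runs.
#' @param seed optional RNG seed (stochastic mode).
#' @param schedule,initial_fractions,total_density,config,first_df passed to
#'   [run_schedule()].
#' @param ... unused.
#' @return A list of `lv_trajectory` objects.
#' @export
simulate.lv_params <- function(object, nsim = 1, seed = NULL, schedule,
                               initial_fractions, total_density = 1,
                               config = sim_config(), first_df = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, run_schedule(object, schedule, initial_fractions,
                               total_density, config, first_df),
            simplify = FALSE)
}
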