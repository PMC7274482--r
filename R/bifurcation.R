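# Endpoint clustering and outcome classification from simulated runs.

# One-dimensional clustering: sort, cut where consecutive gaps exceed tol,
# return cluster means.
cluster_1d <- function(x, tol) {
  x <- sort(x)
  if (length(x) == 1) return(x)
  cuts <- which(diff(x) > tol)
  grp <- rep(seq_len(length(cuts) + 1), diff(c(0, cuts, length(x))))
  as.numeric(tapply(x, grp, mean))
}

#' Classify a two-species outcome from simulated endpoint fractions
#'
#' Clusters the final fractions of species i reached from several initial
#' fractions and maps the cluster structure to an outcome label: a single
#' cluster at a boundary is exclusion, a single interior cluster is
#' coexistence, and clusters at both boundaries are bistability.
#'
#' @param endpoints final fractions of species i, one per initial condition.
#' @param cluster_tol endpoints closer than this are merged into one state.
#' @param boundary_tol cluster centers within this distance of 0 or 1 are
#'   treated as boundary (exclusion) states; finite-depth colony counts
#'   cannot resolve fractions closer to a boundary than roughly one colony
#'   in the plating total, so count-derived endpoints need a wider tolerance.
#' @return An `lv_outcome` object (label, stable states, unstable state
#'   `NA`; separatrices are located separately by [find_separatrix()]).
#' @export
classify_endpoints <- function(endpoints, cluster_tol = 0.02,
                               boundary_tol = 0.05) {
  if (any(!is.finite(endpoints))) {
    stop_lv("lvdilute_invalid_state", "endpoints must be finite fractions")
  }
  centers <- cluster_1d(endpoints, cluster_tol)
  at0 <- centers <= boundary_tol
  at1 <- centers >= 1 - boundary_tol
  interior <- !at0 & !at1
  label <- if (any(at0) && any(at1) && !any(interior)) {
    "BISTABILITY"
  } else if (length(centers) == 1 && any(at1)) {
    "EXCLUSION_I_WINS"
  } else if (length(centers) == 1 && any(at0)) {
    "EXCLUSION_J_WINS"
  } else if (length(centers) == 1) {
    "COEXISTENCE"
  } else {
    "AMBIGUOUS"
  }
  stable <- centers
  stable[at0] <- 0
  stable[at1] <- 1
  structure(list(label = label, stable_states = unique(stable),
                 unstable_state = NA_real_),
            class = "lv_outcome")
}

#' Classify a pair's outcome by brute-force simulation
#'
#' Runs the growth-dilution simulator (or, with `continuous = TRUE`, the
#' continuous-mortality flow) from a grid of initial fractions and
#' classifies the endpoint clusters.  This is the simulation route to the
#' phase diagram; [classify_outcome()] is the analytic one.
#'
#' @param params a two-species [lv_params] object.
#' @param schedule dilution schedule or constant DF (discrete mode), or the
#'   mortality rate `delta` when `continuous = TRUE`.
#' @param inits initial fractions of species 1 to launch from.
#' @param config an [sim_config()].
#' @param continuous use the continuous-mortality flow instead of discrete
#'   transfers.
#' @param t_days integration time per run in continuous mode.
#' @param total_density initial total density (discrete mode).
#' @param cluster_tol,boundary_tol passed to [classify_endpoints()].
#' @return An `lv_outcome` object; attribute `"endpoints"` carries the raw
#'   endpoint map.
#' @export
classify_by_simulation <- function(params, schedule,
                                   inits = c(0.05, 0.275, 0.5, 0.725, 0.95),
                                   config = sim_config(), continuous = FALSE,
                                   t_days = 300, total_density = 1,
                                   cluster_tol = 0.02, boundary_tol = 0.05) {
  assert_lv_params(params)
  if (n_species(params) != 2) {
    stop_lv("lvdilute_invalid_params", "classify_by_simulation is defined for two species")
  }
  endpoints <- vapply(inits, function(f0) {
    if (continuous) {
      st <- integrate_lv(params, c(f0, 1 - f0), t_days, delta = schedule,
                         config = config)
      tot <- sum(st)
      if (tot <= 0) return(NaN)
      st[1] / tot
    } else {
      tr <- run_schedule(params, schedule, c(f0, 1 - f0), total_density, config)
      # under a fluctuating schedule the stationary state is a periodic
      # orbit; average the fractions over the last full period so endpoints
      # from different runs are phase-aligned
      L <- min(length(as_schedule(schedule)$dfs), nrow(tr$fraction))
      mean(tr$fraction[seq(nrow(tr$fraction) - L + 1, nrow(tr$fraction)), 1])
    }
  }, numeric(1))
  out <- classify_endpoints(endpoints, cluster_tol, boundary_tol)
  attr(out, "endpoints") <- data.frame(init = inits, final = endpoints)
  out
}

#' Locate the separatrix of a bistable pair
#'
#' Bisection on the initial fraction of species 1: starting fractions on
#' either side of the separatrix reach different stable states.  Requires
#' the pair to be bistable under the given schedule (the endpoints from the
#' two bracket ends must differ); otherwise a classed
#' `lvdilute_no_separatrix` error is raised.
#'
#' @param params a two-species [lv_params] object.
#' @param schedule dilution schedule or constant DF.
#' @param config an [sim_config()].
#' @param bracket initial search bracket of fractions.
#' @param tol bisection stops once the bracket is narrower than this.
#' @param total_density initial total density passed to [run_schedule()].
#' @return The separatrix (unstable initial fraction), midpoint of the final
#'   bracket.
#' @export
find_separatrix <- function(params, schedule, config = sim_config(),
                            bracket = c(0.01, 0.99), tol = 1e-4,
                            total_density = 1) {
  winner <- function(f0) {
    tr <- run_schedule(params, schedule, c(f0, 1 - f0), total_density, config)
    final_fractions(tr)[1] > 0.5
  }
  lo <- bracket[1]; hi <- bracket[2]
  wlo <- winner(lo); whi <- winner(hi)
  if (wlo == whi) {
    stop_lv("lvdilute_no_separatrix",
            "pair is not bistable under this schedule: both bracket ends reach the same state")
  }
  while (hi - lo >= tol) {
    mid <- (lo + hi) / 2
    if (winner(mid) == wlo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bifurcation diagram over a dilution-factor grid
#'
#' For each constant dilution factor, runs the simulator from each initial
#' fraction, clusters the endpoints into stable states, and inserts the
#' separatrix (unstable branch) wherever two stable states coexist.
#'
#' @param params a two-species [lv_params] object.
#' @param df_grid dilution factors to scan.
#' @param init_grid initial fractions of species 1.
#' @param config an [sim_config()].
#' @param cluster_tol endpoint clustering tolerance.
#' @param cycle_hours cycle duration in hours.
#' @return An object of class `lv_bifurcation`: list with `df`, `states`
#'   (per-DF list with `stable`, `unstable`, `label`) and `endpoints` (the
#'   per-initial-fraction endpoint map as a data frame).
#' @export
bifurcation_diagram <- function(params, df_grid,
                                init_grid = c(0.05, 0.275, 0.5, 0.725, 0.95),
                                config = sim_config(), cluster_tol = 0.02,
                                cycle_hours = 24) {
  if (!length(df_grid) || !length(init_grid)) {
    stop_lv("lvdilute_invalid_config", "df_grid and init_grid must be non-empty")
  }
  df_grid <- sort(normalize_df(df_grid))
  states <- vector("list", length(df_grid))
  maps <- vector("list", length(df_grid))
  for (k in seq_along(df_grid)) {
    df <- df_grid[k]
    sched <- dilution_schedule(df, cycle_hours)
    out <- tryCatch(
      classify_by_simulation(params, sched, inits = init_grid, config = config,
                             cluster_tol = cluster_tol),
      lvdilute_error = function(e) {
        stop_lv("lvdilute_simulation_failure",
                sprintf("at DF %.4g: %s", df, conditionMessage(e)))
      })
    ep <- attr(out, "endpoints")
    unstable <- if (length(out$stable_states) >= 2) {
      find_separatrix(params, sched, config = config)
    } else {
      numeric(0)
    }
    states[[k]] <- list(stable = out$stable_states, unstable = unstable,
                        label = out$label)
    maps[[k]] <- cbind(df = df, ep)
  }
  structure(list(df = df_grid, states = states,
                 endpoints = do.call(rbind, maps), species = params$species),
            class = "lv_bifurcation")
}

#' @export
print.lv_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over %d dilution factors (fraction of %s)\n",
              length(x$df), x$species[1]))
  for (k in seq_along(x$df)) {
    s <- x$states[[k]]
    cat(sprintf("  DF %-10.4g %-18s stable: %s%s\n", x$df[k], s$label,
                paste(signif(s$stable, 3), collapse = ", "),
                if (length(s$unstable)) paste0("  separatrix: ", signif(s$unstable, 3)) else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.lv_bifurcation <- function(x, ...) {
  rows <- lapply(seq_along(x$df), function(k) {
    s <- x$states[[k]]
    data.frame(
      df = x$df[k],
      branch_type = c(rep("stable", length(s$stable)),
                      rep("unstable", length(s$unstable))),
      fraction = c(s$stable, s$unstable)
    )
  })
  do.call(rbind, rows)
}

#' @export
plot.lv_bifurcation <- function(x, ...) {
  d <- as.data.frame(x)
  st <- d[d$branch_type == "stable", ]
  un <- d[d$branch_type == "unstable", ]
  graphics::plot(log10(st$df), st$fraction, pch = 16, ylim = c(0, 1),
                 xlab = "log10 dilution factor",
                 ylab = paste("fraction of", x$species[1]), ...)
  if (nrow(un)) graphics::points(log10(un$df), un$fraction, pch = 1)
  invisible(x)
}

#' Group final community states across trajectories
#'
#' Determines the surviving-species subset of each trajectory (species above
#' the extinction threshold at the final cycle), then clusters final
#' compositions within each subset.  For two species the pairwise outcome
#' label is attached.
#'
#' @param trajectories a list of `lv_trajectory` objects over the same
#'   community.
#' @param config an [sim_config()]; its `extinction_threshold` defines
#'   survival.
#' @param cluster_tol maximum distance (in fraction space, max-norm between
#'   compositions) merged into one state.
#' @return An object of class `lv_states`: data frame `states` (one row per
#'   state: `state`, `label`, `n_trajectories`, mean composition columns),
#'   vector `assignment` mapping each trajectory to a state, logical
#'   `unconverged` flags, and for pairs `outcome` (an outcome label from
#'   [classify_endpoints()]).
#' @export
classify_final_states <- function(trajectories, config = sim_config(),
                                  cluster_tol = 0.05) {
  if (!length(trajectories)) stop_lv("lvdilute_invalid_state", "no trajectories supplied")
  species <- trajectories[[1]]$species
  n <- length(species)
  finals <- t(vapply(trajectories, final_fractions, numeric(n)))
  ab <- t(vapply(trajectories, final_abundances, numeric(n)))
  thr <- max(config$extinction_threshold, .Machine$double.xmin)
  surv <- ab > thr
  key <- apply(surv, 1, function(s) paste(species[s], collapse = "+"))
  unconverged <- !vapply(trajectories, `[[`, logical(1), "converged")

  assignment <- integer(length(trajectories))
  rows <- list()
  sid <- 0
  for (k in unique(key)) {
    idx <- which(key == k)
    comp <- finals[idx, , drop = FALSE]
    taken <- rep(FALSE, length(idx))
    while (any(!taken)) {
      seed_row <- comp[which(!taken)[1], ]
      member <- !taken & apply(comp, 1, function(z) max(abs(z - seed_row)) <= cluster_tol)
      sid <- sid + 1
      assignment[idx[member]] <- sid
      mean_comp <- colMeans(comp[member, , drop = FALSE])
      rows[[sid]] <- data.frame(state = sid, label = k,
                                n_trajectories = sum(member),
                                t(setNames(mean_comp, species)),
                                check.names = FALSE)
      taken <- taken | member
    }
  }
  out <- list(states = do.call(rbind, rows), assignment = assignment,
              unconverged = unconverged, species = species)
  if (n == 2) {
    out$outcome <- classify_endpoints(finals[, 1],
                                      cluster_tol = cluster_tol)$label
  }
  structure(out, class = "lv_states")
}

#' @export
print.lv_states <- function(x, ...) {
  cat(sprintf("Final community states (%d trajectories, %d state(s))\n",
              length(x$assignment), nrow(x$states)))
  print(cbind(x$states[1:3], round(x$states[-(1:3)], 4)), row.names = FALSE)
  if (!is.null(x$outcome)) cat("  pairwise outcome:", x$outcome, "\n")
  if (any(x$unconverged)) {
    cat(sprintf("  warning: %d trajectorie(s) had not converged\n", sum(x$unconverged)))
  }
  invisible(x)
}
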