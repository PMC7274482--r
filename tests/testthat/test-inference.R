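test_that("time-to-threshold estimator matches its closed form and errors", {
  # OD0 1e-3 crossing 0.1 at exactly 10 h: r = log(100)/10
  t <- seq(0, 40, by = 0.25)
  od <- 1e-3 * exp(log(100) / 10 * t)
  expect_equal(estimate_growth_rate(t, od, od0 = 1e-3), log(100) / 10,
               tolerance = 1e-6)
  # never crosses
  expect_error(estimate_growth_rate(t, rep(0.01, length(t)), od0 = 1e-3),
               class = "lvdilute_no_growth")
  # starts above threshold
  expect_error(estimate_growth_rate(t, 0.2 + 0 * t, od0 = 1e-3),
               class = "lvdilute_invalid_curve")
  expect_error(estimate_growth_rate(t, od, od0 = 0.5),
               class = "lvdilute_invalid_curve")
  # negative ODs are clipped with a warning
  odn <- od; odn[1] <- -1e-4
  expect_warning(estimate_growth_rate(t, odn, od0 = 1e-3), "clipped")
})

test_that("estimator recovers logistic rates and absorbs lag as a bias", {
  r <- 0.5 # 1/h
  K <- 1.2
  t <- seq(0, 40, by = 0.25)
  od0 <- 1e-4
  logistic <- function(te) K * od0 * exp(r * te) / (K + od0 * (exp(r * te) - 1))
  est <- estimate_growth_rate(t, logistic(t), od0 = od0)
  expect_lt(abs(est - r) / r, 0.02) # saturation bias only
  # a dead-time lag lowers the estimate (lag absorbed, not corrected)
  est_lag <- estimate_growth_rate(t, logistic(pmax(t - 2, 0)), od0 = od0)
  expect_lt(est_lag, est)
  # invariance under a uniform time-unit rescaling
  est_days <- estimate_growth_rate(t / 24, logistic(t), od0 = od0)
  expect_equal(est_days, est * 24, tolerance = 1e-10)
})

test_that("replicate aggregation gives mean and SEM", {
  a <- aggregate_growth_rates(c(0.4, 0.4, 0.4))
  expect_equal(a$estimate, 0.4)
  expect_equal(a$sem, 0)
  b <- aggregate_growth_rates(c(0.3, 0.5))
  expect_equal(b$estimate, 0.4)
  expect_equal(b$sem, 0.1)
  expect_error(aggregate_growth_rates(numeric(0)), class = "lvdilute_invalid_curve")
  # SEM tracks the analytic SD/sqrt(n) for known spread
  set.seed(81)
  x <- rnorm(400, 0.5, 0.05)
  expect_equal(aggregate_growth_rates(x)$sem, sd(x) / 20)
})

test_that("boundary dilution factors invert to competition coefficients", {
  # delta* = 0.25, r_i = 1, r_j = 0.5 -> alpha = 1.5 (inverse of the
  # critical-delta example)
  expect_equal(estimate_alpha_from_boundary(delta_to_df(0.25), 1, 0.5), 1.5)
  expect_equal(estimate_alpha_from_boundary(1, 1, 0.5), 1) # delta* = 0
  expect_error(estimate_alpha_from_boundary(1e6, 1, 0.5),
               class = "lvdilute_washout")
  # exact round trip with critical_delta
  set.seed(91)
  hits <- 0
  while (hits < 15) {
    a <- runif(1, 0.3, 2.5); ri <- runif(1, 5, 30); rj <- runif(1, 5, 30)
    ds <- tryCatch(critical_delta(a, ri, rj), lvdilute_no_crossing = function(e) NULL)
    if (is.null(ds) || ds == 0) next
    hits <- hits + 1
    expect_equal(estimate_alpha_from_boundary(delta_to_df(ds), ri, rj), a,
                 tolerance = 1e-9)
  }
})

fit_design <- function(step = 0.25, days = 60) {
  experiment_design(
    dfs = 10^seq(0.75, 3.75, by = step), days = days,
    initial_fractions = c(0.002, 0.05, 0.275, 0.5, 0.725, 0.95, 0.998))
}

fit_config <- function() sim_config(max_cycles = 60, conv_eps = 1e-7)

test_that("synth-then-fit recovers parameters on a noiseless dense design", {
  p <- switch_pair()
  b <- generate_bundle(fit_design(), params = p, seed = 7, config = fit_config())
  f <- lv_fit(b, use = "trajectories")
  # growth rates within 2 percent (time-to-threshold saturation bias only)
  expect_lt(max(f$recovery$rel_error[1:2]), 0.02)
  # coefficients within the documented half-grid-step bound
  for (k in seq_len(nrow(f$boundaries))) {
    i <- f$boundaries$affected[k]; j <- f$boundaries$agent[k]
    expect_lt(abs(log(f$alpha[i, j] / p$alpha[i, j])),
              f$boundaries$log_alpha_bound[k])
  }
  # the boundary DF round-trips through critical_delta at the fitted values
  for (k in seq_len(nrow(f$boundaries))) {
    i <- f$boundaries$affected[k]; j <- f$boundaries$agent[k]
    expect_equal(delta_to_df(critical_delta(f$alpha[i, j], f$r[[i]], f$r[[j]])),
                 f$boundaries$df_mid[k], tolerance = 1e-6)
  }
  # fitted model predicts the phase-diagram labels across the switch
  expect_equal(predict(f, df = c(5, 316, 8000)),
               c("EXCLUSION_J_WINS", "BISTABILITY", "EXCLUSION_I_WINS"))
  expect_named(coef(f), c("r", "alpha"))
})

test_that("recovery stays within bounds that tighten as the grid is refined", {
  # the realized error is a quantization error, so it is the reported
  # half-grid-step bound that must shrink with the spacing and contain the
  # error at every resolution
  p <- switch_pair()
  bounds <- numeric(0)
  for (step in c(1, 0.5, 0.25)) {
    b <- generate_bundle(fit_design(step), params = p, seed = 7,
                         config = fit_config())
    f <- lv_fit(b, use = "trajectories")
    for (k in seq_len(nrow(f$boundaries))) {
      i <- f$boundaries$affected[k]; j <- f$boundaries$agent[k]
      expect_lt(abs(log(f$alpha[i, j] / p$alpha[i, j])),
                f$boundaries$log_alpha_bound[k])
    }
    bounds <- c(bounds, max(f$boundaries$log_alpha_bound))
  }
  expect_true(all(diff(bounds) < 0))
})

test_that("designs with no outcome change are reported as uninformative", {
  p <- coexist_pair()
  des <- experiment_design(dfs = c(10, 31.6, 100), days = 25,
                           initial_fractions = c(0.1, 0.5, 0.9))
  b <- generate_bundle(des, params = p, seed = 3,
                       config = sim_config(max_cycles = 25))
  expect_error(lv_fit(b, use = "trajectories"), class = "lvdilute_uninformative")
  expect_error(lv_fit(b, use = "trajectories"), "COEXISTENCE")
})

test_that("count-based recovery degrades gracefully with plating depth", {
  p <- switch_pair()
  # trajectories are deterministic: simulate once, then redraw platings
  base <- generate_bundle(fit_design(0.5), params = p, seed = 7,
                          config = fit_config())
  err_at_depth <- function(platings, seed) {
    set.seed(seed)
    des <- base$design
    des$platings <- platings
    counts <- do.call(rbind, lapply(seq_along(base$trajectories), function(k)
      generate_count_tables(base$trajectories[[k]], des,
                            condition = base$trajectory_index$condition[k])))
    b <- base
    b$counts <- counts
    f <- tryCatch(lv_fit(b, use = "counts"),
                  lvdilute_uninformative = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    max(abs(log(c(f$alpha[1, 2] / p$alpha[1, 2],
                  f$alpha[2, 1] / p$alpha[2, 1]))), na.rm = TRUE)
  }
  e1 <- vapply(1:12, function(s) err_at_depth(1, s), numeric(1))
  e4 <- vapply(1:12, function(s) err_at_depth(4, s), numeric(1))
  expect_lte(median(e4, na.rm = TRUE), median(e1, na.rm = TRUE) + 1e-9)
})
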