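test_that("parameter validation enforces the model's invariants", {
  expect_s3_class(lv_params(r = 1, alpha = matrix(1, 1, 1)), "lv_params")
  expect_error(lv_params(r = c(1, -1), alpha = diag(2)), class = "lvdilute_invalid_params")
  expect_error(lv_params(r = c(1, 1), alpha = matrix(1, 3, 3)), class = "lvdilute_invalid_params")
  expect_error(lv_params(r = c(1, 1), alpha = matrix(c(1, -0.2, 0.5, 1), 2)),
               class = "lvdilute_invalid_params")
  expect_error(lv_params(r = c(1, 1), alpha = matrix(c(2, 0.5, 0.5, 2), 2)),
               class = "lvdilute_invalid_params")
  # per-hour rates are converted to the canonical 1/day
  p <- lv_params(r = c(0.5, 0.25), alpha = matrix(c(1, .1, .1, 1), 2),
                 unit = "per_hour")
  expect_equal(unname(p$r), c(12, 6))
})

test_that("reparametrization matches the closed form and its identities", {
  # delta = 0 identity
  expect_identical(reparametrize(0.8, 1.3, 0.9, 0), 0.8)
  # symbolic substitution: 1.5 * (1 - 0.25/0.5) / (1 - 0.25/1.0)
  expect_equal(reparametrize(1.5, 1.0, 0.5, 0.25), 1.0)
  # 0.8 * (1 - 0.2/0.4) / (1 - 0.2/0.7) = 0.8 * 0.5 / (5/7)
  expect_equal(reparametrize(0.8, 0.7, 0.4, 0.2), 0.56)
  # washout raised, naming the species that cannot sustain itself
  expect_error(reparametrize(1.0, 1.0, 0.3, 0.5), class = "lvdilute_washout")
  expect_error(reparametrize(1.0, 0.2, 1.0, 0.5), class = "lvdilute_washout")
})

test_that("mortality rescaling is an exact change of variables for the dynamics", {
  # Integrating the mortality model directly and integrating the
  # reparametrized (mortality-free) model then mapping back through
  # N_i = Ntilde_i (1 - delta/r_i) must give the same trajectories.
  set.seed(11)
  for (k in 1:6) {
    p <- sample_params(2, "random")
    delta <- runif(1, 0.05, 0.7) * min(p$r)
    eff <- reparametrize_params(p, delta)
    x0 <- runif(2, 0.01, 0.6)
    times <- seq(0, 3, by = 0.25)
    direct <- integrate_lv(p, x0, times, delta = delta)
    scale <- 1 - delta / p$r
    mapped <- integrate_lv(eff, x0 / scale, times) *
      rep(scale, each = length(times))
    expect_equal(unname(direct), unname(mapped), tolerance = 1e-6)
  }
})

test_that("increasing mortality favors the fast grower", {
  set.seed(21)
  for (k in 1:10) {
    p <- sample_params(2, "random")
    fast <- which.max(p$r); slow <- 3 - fast
    dgrid <- seq(0, 0.95 * min(p$r), length.out = 40)
    at_fs <- vapply(dgrid, function(d)
      reparametrize(p$alpha[fast, slow], p$r[[fast]], p$r[[slow]], d), 0)
    at_sf <- vapply(dgrid, function(d)
      reparametrize(p$alpha[slow, fast], p$r[[slow]], p$r[[fast]], d), 0)
    expect_true(all(diff(at_fs) <= 1e-12))  # inhibition felt by fast non-increasing
    expect_true(all(diff(at_sf) >= -1e-12)) # inhibition felt by slow non-decreasing
  }
})

test_that("outcome classification follows the unit-coefficient phase diagram", {
  expect_equal(classify_outcome(0.5, 0.7)$label, "COEXISTENCE")
  expect_equal(classify_outcome(1.5, 2.0)$label, "BISTABILITY")
  expect_equal(classify_outcome(1.5, 0.5)$label, "EXCLUSION_J_WINS")
  expect_equal(classify_outcome(0.5, 1.5)$label, "EXCLUSION_I_WINS")
  expect_error(classify_outcome(1, 0.5), class = "lvdilute_degenerate_boundary")
  expect_error(classify_outcome(0.5, 1 + 1e-12), class = "lvdilute_degenerate_boundary")
  # coexistence interior state from the nullcline intersection
  out <- classify_outcome(0.5, 0.5)
  expect_equal(out$stable_states, 0.5)
  # bistable unstable fraction: both 1.5 -> rescaled abundances (0.4, 0.4)
  expect_equal(classify_outcome(1.5, 1.5)$unstable_state, 0.5)
})

test_that("interior fixed point solves the nullclines and grades stability", {
  # symmetric coexistence: (1 - a) / (1 - a^2) = 1/(1+a) = 2/3 at a = 0.5
  p <- lv_params(r = c(5, 5), alpha = matrix(c(1, .5, .5, 1), 2))
  eq <- interior_fixed_point(p, delta = 0)
  expect_equal(unname(eq$abundances), c(2, 2) / 3)
  expect_true(eq$stable)

  # both coefficients 1.5: interior point (0.4, 0.4), unstable by the
  # eigenvalue oracle on the Jacobian
  pb <- lv_params(r = c(5, 5), alpha = matrix(c(1, 1.5, 1.5, 1), 2))
  eqb <- interior_fixed_point(pb, delta = 0)
  expect_equal(unname(eqb$abundances), c(0.4, 0.4))
  J <- -diag(eqb$abundances * pb$r) %*% pb$alpha
  expect_equal(max(Re(eigen(J)$values)) > 0, !eqb$stable)
  expect_false(eqb$stable)

  # nullcline residuals vanish at the returned point, with and without delta
  set.seed(31)
  for (k in 1:8) {
    d <- draw_pair_and_delta()
    eq <- tryCatch(interior_fixed_point(d$params, d$delta),
                   lvdilute_no_interior = function(e) NULL)
    if (is.null(eq)) next
    N <- eq$abundances
    res <- d$params$r * (1 - as.numeric(d$params$alpha %*% N)) - d$delta
    expect_lt(max(abs(res)), 1e-10)
  }

  # exclusion-regime parameters have no interior equilibrium
  pe <- lv_params(r = c(5, 5), alpha = matrix(c(1, 1.5, 0.5, 1), 2, byrow = TRUE))
  expect_error(interior_fixed_point(pe), class = "lvdilute_no_interior")
})

test_that("critical mortality solves alpha_tilde = 1 and round-trips", {
  expect_equal(critical_delta(1.5, 1.0, 0.5), 0.25)
  expect_identical(critical_delta(1, 3, 7), 0)
  # (1 - 1.5) / (1/0.5 - 1.5/1.0) = -1 < 0: no crossing in range
  expect_error(critical_delta(1.5, 0.5, 1.0), class = "lvdilute_no_crossing")

  set.seed(41)
  hits <- 0
  while (hits < 20) {
    a <- runif(1, 0.2, 2.5); ri <- runif(1, 0.3, 2); rj <- runif(1, 0.3, 2)
    ds <- tryCatch(critical_delta(a, ri, rj), lvdilute_no_crossing = function(e) NULL)
    if (is.null(ds)) next
    hits <- hits + 1
    expect_lt(abs(reparametrize(a, ri, rj, ds) - 1), 1e-10)
  }
})

test_that("dilution factors map logarithmically to mortality rates", {
  expect_identical(df_to_delta(1), 0)
  expect_equal(df_to_delta(1e3), 3 * log(10))
  expect_equal(df_to_delta(100, cycle_hours = 12), 2 * log(10) * 2)
  for (x in 10^(1:6)) expect_equal(delta_to_df(df_to_delta(x)), x)
  expect_error(df_to_delta(0), class = "lvdilute_invalid_dilution")
  # transfer-fraction notation is normalized to fold dilution
  expect_message(d <- df_to_delta(1e-3), "normalizing")
  expect_equal(d, 3 * log(10))
})

test_that("fluctuating schedules time-average as a geometric mean", {
  expect_equal(schedule_equivalent_df(c(10, 1e5)), 1e3)
  expect_equal(schedule_equivalent_df(c(1e2, 1e4)), 1e3)
  expect_equal(schedule_equivalent_df(rep(100, 7)), 100)
  # permutation invariance (timing independence)
  set.seed(51)
  for (k in 1:10) {
    dfs <- 10^runif(sample(2:6, 1), 0, 5)
    expect_equal(schedule_equivalent_df(sample(dfs)),
                 schedule_equivalent_df(dfs))
  }
})

test_that("compiled dynamics agree with a plain-R right-hand side", {
  p <- bistable_pair()
  x0 <- c(0.02, 0.05)
  ref <- deSolve::ode(y = x0, times = c(0, 1), func = lvdilute:::lv_rhs_r,
                      parms = list(r = p$r, alpha = p$alpha, delta = 0.4),
                      rtol = 1e-10, atol = 1e-12)
  got <- integrate_lv(p, x0, 1, delta = 0.4,
                      config = sim_config(rtol = 1e-10, atol = 1e-12))
  expect_equal(unname(got), unname(ref[2, -1]), tolerance = 1e-8)
})

test_that("phase table marks washout and matches raw coefficients at delta 0", {
  p <- switch_pair()
  tab <- phase_table(p, delta_grid = c(0, 1, 50))
  expect_equal(tab$alpha_tilde_ij[1], unname(p$alpha[1, 2]))
  expect_equal(tab$alpha_tilde_ji[1], unname(p$alpha[2, 1]))
  expect_match(tab$label[3], "WASHOUT")
  # along a DF grid spanning the switch, each label change matches a
  # critical-delta crossing
  tab2 <- phase_table(p, df_grid = 10^seq(0.5, 3.9, by = 0.1))
  lab <- rle(tab2$label)$values
  expect_equal(lab, c("EXCLUSION_J_WINS", "BISTABILITY", "EXCLUSION_I_WINS"))
})
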