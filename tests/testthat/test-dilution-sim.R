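test_that("one growth cycle follows the logistic closed form", {
  p1 <- lv_params(r = 1, alpha = matrix(1, 1, 1))
  # monoculture at carrying capacity stays there
  expect_equal(grow_cycle(1, p1, 24), 1, tolerance = 1e-8)
  # the empty community is absorbing
  p2 <- coexist_pair()
  expect_identical(grow_cycle(c(0, 0), p2, 24), c(0, 0))
  expect_equal(grow_cycle(c(0, 0.5), p2, 24)[1], 0)
  # closed-form logistic oracle: N0 e^r / (1 + N0 (e^r - 1)) after 24 h
  n0 <- 0.01
  oracle <- n0 * exp(1) / (1 + n0 * (exp(1) - 1))
  expect_equal(grow_cycle(n0, p1, 24), oracle, tolerance = 1e-7)
})

test_that("dilution divides abundances and applies the extinction threshold", {
  cfg <- sim_config(extinction_threshold = 1e-8)
  expect_equal(apply_dilution(0.5, 10, cfg), 0.05)
  expect_identical(apply_dilution(1e-7, 1e4, cfg), 0)
  expect_equal(apply_dilution(c(0.5, 1e-7), 10, cfg), c(0.05, 1e-8))
  # dilution never increases abundance
  set.seed(61)
  for (k in 1:20) {
    x <- runif(3, 0, 1)
    expect_true(all(apply_dilution(x, 10^runif(1, 0, 5), cfg) <= x))
  }
})

test_that("stochastic dilution matches the binomial extinction probability", {
  scale <- 1e4
  cfg <- sim_config(stochastic = TRUE, cells_per_unit = scale)
  df <- 500
  n0 <- 0.02               # 200 cells, expected survivors 0.4
  p_ext <- dbinom(0, size = n0 * scale, prob = 1 / df)
  set.seed(71)
  nrep <- 4000
  ext <- replicate(nrep, apply_dilution(n0, df, cfg) == 0)
  se <- sqrt(p_ext * (1 - p_ext) / nrep)
  expect_lt(abs(mean(ext) - p_ext), 5 * se)
})

test_that("serial transfers preserve symmetry and the net-growth threshold", {
  # fully symmetric pair started 50:50 stays at 50:50
  psym <- lv_params(r = c(8, 8), alpha = matrix(c(1, .6, .6, 1), 2))
  tr <- run_schedule(psym, 100, c(0.5, 0.5), config = sim_config(max_cycles = 30))
  expect_true(all(abs(tr$fraction[, 1] - 0.5) < 1e-9))

  # single species persists iff DF < e^(r T)
  p1 <- lv_params(r = 3, alpha = matrix(1, 1, 1))
  cfg <- sim_config(max_cycles = 60)
  lo <- run_schedule(p1, exp(3) * 0.5, 1, config = cfg)
  hi <- run_schedule(p1, exp(3) * 2.0, 1, config = cfg)
  expect_gt(final_abundances_of(lo), 0)
  expect_identical(unname(final_abundances_of(hi)), 0)
})

test_that("bistable parameters send extreme starting fractions to opposite states", {
  p <- symmetric_bistable_pair()
  cfg <- sim_config(max_cycles = 100)
  lo <- run_schedule(p, 100, c(0.05, 0.95), config = cfg)
  hi <- run_schedule(p, 100, c(0.95, 0.05), config = cfg)
  expect_lt(tail(lo$fraction[, 1], 1), 0.01)
  expect_gt(tail(hi$fraction[, 1], 1), 0.99)
  # extinct species never revive
  z <- run_schedule(p, 1e3, c(1, 0), config = cfg)
  expect_true(all(z$abundance[, 2] == 0))
})

test_that("subdividing a cycle converges to the continuous-mortality flow", {
  p <- coexist_pair()
  D <- 1e3
  days <- 6
  cont <- integrate_lv(p, c(0.3, 0.2), days, delta = df_to_delta(D))
  err <- vapply(c(1, 2, 4, 8), function(m) {
    cfgm <- sim_config(extinction_threshold = 0, conv_eps = 0,
                       max_cycles = days * m)
    tr <- run_schedule(p, dilution_schedule(D^(1 / m), 24 / m), c(0.6, 0.4),
                       total_density = 0.5, config = cfgm)
    sum(abs(final_abundances_of(tr) - cont))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("separatrix location is symmetric, definitional, and shifts with DF", {
  p <- symmetric_bistable_pair()
  cfg <- sim_config(max_cycles = 150)
  s <- find_separatrix(p, 100, config = cfg)
  expect_equal(s, 0.5, tolerance = 1e-3)

  # runs launched just either side of the separatrix diverge
  ps <- switch_pair()
  s2 <- find_separatrix(ps, 316, config = cfg)
  lo <- run_schedule(ps, 316, c(s2 - 0.01, 1 - s2 + 0.01), config = cfg)
  hi <- run_schedule(ps, 316, c(s2 + 0.01, 1 - s2 - 0.01), config = cfg)
  expect_lt(tail(lo$fraction[, 1], 1), 0.5)
  expect_gt(tail(hi$fraction[, 1], 1), 0.5)

  # within the bistable window the basin of the fast grower widens with DF
  s_low <- find_separatrix(ps, 100, config = cfg)
  expect_gt(s_low, s2)

  # coexisting pair has no separatrix
  expect_error(find_separatrix(coexist_pair(), 100, config = cfg),
               class = "lvdilute_no_separatrix")
})

test_that("bifurcation diagram reproduces the dominance -> bistability -> dominance pattern", {
  ps <- switch_pair()
  cfg <- sim_config(max_cycles = 150)
  bd <- bifurcation_diagram(ps, df_grid = 10^seq(1, 3.5, by = 0.5),
                            config = cfg)
  labs <- vapply(bd$states, `[[`, "", "label")
  expect_equal(labs[1], "EXCLUSION_J_WINS")       # slow grower wins at DF 10
  expect_equal(labs[length(labs)], "EXCLUSION_I_WINS") # fast grower at the top
  expect_true("BISTABILITY" %in% labs)
  # every separatrix lies strictly between two distinct stable endpoints
  for (st in bd$states) {
    if (length(st$unstable)) {
      expect_gt(st$unstable, min(st$stable))
      expect_lt(st$unstable, max(st$stable))
    }
  }
  # a wholly coexisting pair yields a single interior branch everywhere
  bd2 <- bifurcation_diagram(coexist_pair(), df_grid = c(10, 100),
                             config = cfg)
  for (st in bd2$states) {
    expect_equal(st$label, "COEXISTENCE")
    expect_length(st$stable, 1)
  }
})

test_that("final-state grouping is order-invariant and labels survivors", {
  p <- symmetric_bistable_pair()
  cfg <- sim_config(max_cycles = 100)
  trs <- lapply(c(0.05, 0.3, 0.7, 0.95), function(f)
    run_schedule(p, 100, c(f, 1 - f), config = cfg))
  st <- classify_final_states(trs, cfg)
  expect_equal(st$outcome, "BISTABILITY")
  expect_equal(nrow(st$states), 2)
  st_rev <- classify_final_states(rev(trs), cfg)
  expect_setequal(st$states$label, st_rev$states$label)

  # trio: two alternative two-species coexistence states
  pt <- trio_params()
  inits <- trio_inits()
  trs3 <- lapply(seq_len(nrow(inits)), function(i)
    run_schedule(pt, 1e3, inits[i, ], config = sim_config(max_cycles = 150)))
  st3 <- classify_final_states(trs3, cfg)
  expect_true(all(st3$states$label %in% c("Pp+Ea", "Pv+Ea")))
  expect_setequal(unique(st3$states$label), c("Pp+Ea", "Pv+Ea"))
})

test_that("a fluctuating schedule reaches the states of its time-averaged constant", {
  # trio at constant DF 1e3 vs alternating 10 / 1e5 (same geometric mean):
  # each starting composition must reach the same final state
  pt <- trio_params()
  cfg <- sim_config(max_cycles = 150)
  inits <- trio_inits()
  surviving <- function(tr) paste(tr$species[final_abundances_of(tr) >
                                               1e-8], collapse = "+")
  for (i in seq_len(nrow(inits))) {
    cst <- run_schedule(pt, 1e3, inits[i, ], config = cfg)
    flc <- run_schedule(pt, dilution_schedule(c(10, 1e5)), inits[i, ],
                        config = cfg)
    expect_equal(surviving(flc), surviving(cst))
  }
})

test_that("simulation classification agrees with the analytic phase diagram", {
  # matched continuous delta, away from boundaries (cross-module oracle)
  ps <- switch_pair()
  cfg <- sim_config(max_cycles = 200)
  for (df in c(10, 316, 6000)) {
    sim <- classify_by_simulation(ps, df, config = cfg,
                                  inits = c(0.02, 0.35, 0.65, 0.98))
    ana <- classify_outcome(alpha_tilde_pair(ps, df_to_delta(df))[1],
                            alpha_tilde_pair(ps, df_to_delta(df))[2])
    expect_equal(sim$label, ana$label)
  }
})
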