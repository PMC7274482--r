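# Shared fixtures, built in code.

# A pair whose outcome switches from slow-grower to fast-grower dominance
# across DF 10..1e4, passing through bistability at DF 10^2.5.
switch_pair <- function() sample_params(2, "switch_bistable", seed = 42)

# Simple fixed pairs (rates in 1/day).
coexist_pair <- function() {
  lv_params(r = c(15, 12), alpha = matrix(c(1, 0.5, 0.5, 1), 2, byrow = TRUE))
}

bistable_pair <- function() {
  lv_params(r = c(20, 10), alpha = matrix(c(1, 1.5, 2.0, 1), 2, byrow = TRUE))
}

symmetric_bistable_pair <- function() {
  lv_params(r = c(12, 12), alpha = matrix(c(1, 1.6, 1.6, 1), 2, byrow = TRUE))
}

# Three-species community built from a sampled switching pair (Pp fast, Pv
# slow, bistable at DF 1e3 with a mid-range separatrix under both constant
# and alternating schedules) plus a third species that coexists with each:
# two alternative two-species coexistence states, as in a soil-bacteria trio.
trio_params <- function() {
  pp <- sample_params(2, "switch_bistable", seed = 31, df_low = 10,
                      df_high = 1e5)
  a <- matrix(c(1, pp$alpha[1, 2], 0.75,
                pp$alpha[2, 1], 1, 0.60,
                0.60, 0.85, 1), 3, byrow = TRUE)
  lv_params(r = c(pp$r[[1]], pp$r[[2]], 16), alpha = a,
            species = c("Pp", "Pv", "Ea"), K = c(1.2, 1.1, 1.3))
}

# Four starting compositions lying well inside the trio's basins (central
# compositions near the basin boundary are excluded, as near-separatrix
# starts equilibrate arbitrarily slowly and may cross under perturbations).
trio_inits <- function() {
  rbind(c(0.10, 0.70, 0.20), c(0.70, 0.10, 0.20),
        c(0.55, 0.15, 0.30), c(0.15, 0.55, 0.30))
}

final_fractions_of <- function(tr) tr$fraction[nrow(tr$fraction), ]
final_abundances_of <- function(tr) tr$abundance[nrow(tr$abundance), ]

# Effective coefficients of a pair at mortality delta, as a c(ij, ji) pair.
alpha_tilde_pair <- function(params, delta) {
  c(reparametrize(params$alpha[1, 2], params$r[[1]], params$r[[2]], delta),
    reparametrize(params$alpha[2, 1], params$r[[2]], params$r[[1]], delta))
}

# Brute-force outcome oracle: integrate the continuous-mortality flow from a
# grid of initial fractions until stationary, then cluster endpoints.
oracle_outcome <- function(params, delta,
                           inits = c(0.002, seq(0.1, 0.9, by = 0.1), 0.998),
                           chunk_days = 250, max_chunks = 12) {
  endpoints <- vapply(inits, function(f0) {
    st <- c(f0, 1 - f0) * 0.5
    for (k in seq_len(max_chunks)) {
      nxt <- integrate_lv(params, st, chunk_days, delta = delta)
      if (max(abs(nxt - st)) < 1e-7) { st <- nxt; break }
      st <- nxt
    }
    if (sum(st) <= 0) return(NaN)
    st[1] / sum(st)
  }, numeric(1))
  classify_endpoints(endpoints, cluster_tol = 0.02, boundary_tol = 0.02)$label
}

# Random valid (params, delta) draw away from the degenerate boundary.
draw_pair_and_delta <- function(margin = 0.05) {
  repeat {
    p <- sample_params(2, "random")
    d <- runif(1, 0, 0.8 * min(p$r))
    at <- tryCatch(alpha_tilde_pair(p, d), lvdilute_error = function(e) NULL)
    if (is.null(at)) next
    if (min(abs(at - 1)) > margin) return(list(params = p, delta = d))
  }
}
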