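# Shared fixtures for the test suite.

# A generic screened parameter set used by oracle comparisons.
generic_params <- function(...) {
  fp_params(
    c_S_to_F = 12.3, c_S_to_N = 0.8, kappa_F = 0.37, kappa_N = 0.051,
    K_N_to_F = 4.2, K_F_to_N = 77, kappa_F_to_S = 0.9, ...
  )
}

# Degenerate parameter set for linear / dilution-only test systems.
degenerate_params <- function(alpha = 0, gamma = 0, D_S = 0, ...) {
  fp_params(
    c_S_to_F = 1, c_S_to_N = 1, kappa_F = 1, kappa_N = 1,
    K_N_to_F = 1, K_F_to_N = 1, kappa_F_to_S = 0,
    alpha_F = alpha, alpha_N = alpha, alpha_S = alpha,
    gamma_F = gamma, gamma_N = gamma, gamma_S = gamma,
    D_S = D_S, ...
  )
}

# Short simulation defaults used where the full 60 h run is not needed.
short_growth <- function(t_end = 2, ...) {
  growth_schedule("linear", t_end = t_end, ...)
}

# Memoised scaled-down screen shared by the acceptance checks
# (4 chains x 2500 visits, pinned seed, classified). Multiple chains
# mirror the multi-chain design of the full screen: the random walk is
# strongly autocorrelated, so ensemble statistics need several
# independent chains.
.screen_env <- new.env(parent = emptyenv())
acceptance_screen <- function() {
  if (is.null(.screen_env$cls)) {
    scr <- run_screen(n_chains = 4, n_visits = 2500, seed = 42)
    .screen_env$cls <- classify_screen(scr)
  }
  .screen_env$cls
}

# fraction of successes satisfying `cond`, with a chain-cluster-robust
# 95% half-width (the walk is autocorrelated, so per-visit binomial
# CIs would be miscalibrated)
cluster_fraction <- function(succ, cond) {
  f <- mean(cond)
  per <- tapply(cond, succ$chain, mean)
  per <- per[!is.na(per)]
  half <- if (length(per) > 1)
    stats::qt(0.975, length(per) - 1) * stats::sd(per) / sqrt(length(per))
  else 1.96 * sqrt(f * (1 - f) / length(cond))
  list(f = f, half = half)
}

# Reference networks of a class from the shipped cache, as fp_params.
cache_networks <- function(sens_class, n) {
  tbl <- reference_networks(sens_class, n)
  lapply(seq_len(nrow(tbl)), function(i) as_fp_params(tbl[i, 1:7]))
}
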