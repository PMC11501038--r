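test_that("reaction rates match the thermodynamic model at reference points", {
  # at the origin with unit basal activation the occupancy is 1/2
  p <- fp_params(1, 1, 1, 1, 1, 1, 1, alpha_F = 0.1, alpha_N = 0.1,
                 gamma_F = 0.72, gamma_N = 0.72)
  expect_equal(reaction_rate_F(0, 0, 0, p), 0.05)
  expect_equal(reaction_rate_N(0, 0, 0, p), 0.05)

  # repressor-dominated limit: production -> 0, only degradation remains
  expect_equal(reaction_rate_F(1, 1e9, 5, p), -0.72, tolerance = 1e-6)
  expect_equal(reaction_rate_N(1e9, 3, 5, p), -0.72 * 3, tolerance = 1e-5)

  # generic point against an independently computed symbolic value
  q <- generic_params()
  expect_equal(reaction_rate_F(2, 3, 5, q), 1.8393911244116300,
               tolerance = 1e-12)
  expect_equal(reaction_rate_N(2, 3, 5, q), -2.1599753482612296,
               tolerance = 1e-12)

  expect_error(reaction_rate_F(-1, 0, 0, p), "non-negative")
  expect_error(reaction_rate_N(0, 0, -2, p), "non-negative")
})

test_that("reaction rates are monotone in the signalling inputs", {
  p <- generic_params()
  S <- seq(0, 50, length.out = 20)
  rF <- reaction_rate_F(rep(1, 20), rep(2, 20), S, p)
  expect_true(all(diff(rF) > 0))            # increasing in Shh
  N <- seq(0, 50, length.out = 20)
  rF <- reaction_rate_F(rep(1, 20), N, rep(5, 20), p)
  expect_true(all(diff(rF) < 0))            # decreasing in repressor
  rN <- reaction_rate_N(seq(0, 50, length.out = 20), rep(2, 20),
                        rep(5, 20), p)
  expect_true(all(diff(rN) < 0))
  # bounded by production minus degradation
  expect_true(all(reaction_rate_F(0, 0, 10^(0:6), p) <= p$alpha_F))
})

test_that("floor-plate Shh production saturates and respects the off switches", {
  p <- generic_params()
  expect_equal(shh_production(0, p), 0)
  expect_equal(shh_production(2, p), 231.42857142857143, tolerance = 1e-12)
  expect_equal(shh_production(1e12, p), p$alpha_S, tolerance = 1e-9)
  p0 <- as_fp_params(p, kappa_F_to_S = 0)
  expect_equal(shh_production(c(0, 1, 100), p0), c(0, 0, 0))
  F <- seq(0, 100, length.out = 30)
  expect_true(all(diff(shh_production(F, p)) >= 0))
})

test_that("analytic decay length is sqrt(D/gamma)", {
  expect_equal(decay_length(1, 1), 1)
  expect_equal(decay_length(4, 1), 2)
  expect_equal(decay_length(0.11, 2e-4), 23.45207880, tolerance = 1e-8)
  # the same value in hour units
  expect_equal(decay_length(396, 0.72), decay_length(0.11, 2e-4))
  expect_error(decay_length(0, 1), "positive")
  expect_error(decay_length(1, -1), "positive")
})

test_that("parameter sets validate their fields", {
  expect_error(fp_params(-1, 1, 1, 1, 1, 1, 1), "positive")
  expect_error(fp_params(1, 1, 1, 1, 1, 1, -0.1), ">= 0")
  expect_error(fp_params(1, 1, 1, 1, 1, 1, 1, m_N_to_F = 0.5), ">= 1")
  expect_error(fp_params(1, 1, 1, 1, 1, 1, NA), "finite")
  # kappa_F_to_S may be exactly zero (Shh^FP off)
  expect_s3_class(fp_params(1, 1, 1, 1, 1, 1, 0), "fp_params")
})

test_that("parameter sets round-trip through JSON with explicit defaults", {
  p <- generic_params()
  js <- params_to_json(p)
  q <- params_from_json(js)
  expect_equal(unclass(q), unclass(p))
  # fixed defaults are emitted explicitly
  for (nm in c("alpha_F", "gamma_S", "D_S", "m_N_to_F"))
    expect_match(as.character(js), nm, fixed = TRUE)
  tmp <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, tmp)
  expect_equal(unclass(params_from_json(tmp)), unclass(p))
})

test_that("as_fp_params accepts rows and applies overrides", {
  row <- sample_params(1)
  p <- as_fp_params(row)
  expect_s3_class(p, "fp_params")
  expect_equal(p$c_S_to_F, row$c_S_to_F)
  expect_equal(p$alpha_F, 360)  # defaults filled in
  p0 <- as_fp_params(p, kappa_F_to_S = 0, gamma_N = 1.44)
  expect_equal(p0$kappa_F_to_S, 0)
  expect_equal(p0$gamma_N, 1.44)
  expect_equal(p0$c_S_to_F, p$c_S_to_F)
})

test_that("growth schedules reproduce the stated laws", {
  lin <- growth_schedule("linear")
  expect_equal(tissue_length(lin, 0), 100)
  expect_equal(tissue_length(lin, 60), 400)
  expect_equal(tissue_growth_rate(lin, c(0, 30)), c(5, 5))
  none <- growth_schedule("none")
  expect_equal(tissue_length(none, c(0, 60)), c(100, 100))
  ex <- growth_schedule("exponential")
  expect_equal(tissue_length(ex, 0), 100)
  expect_equal(tissue_length(ex, 43.3), 100 * exp(1))
  t <- seq(0, 60, by = 5)
  expect_true(all(diff(tissue_length(ex, t)) > 0))
})

test_that("source configurations enforce their invariants", {
  pulse <- source_config("pulse", S_init = 100)
  expect_equal(pulse$j_shh, 0)
  flux <- source_config("flux", j_shh = 0.1)
  expect_equal(flux$S_init, 0)
  expect_error(source_config("flux_off", j_shh = 1), "t_off")
  fo <- source_config("flux_off", j_shh = 1, t_off = 10)
  expect_equal(fo$t_off, 10)
})
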