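test_that("uniform sampling respects ranges and is log-uniform", {
  set.seed(123)
  d <- sample_params(1e4)
  expect_equal(nrow(d), 1e4)
  # alpha 0.001: with 5 tests under a fixed seed this keeps the false-
  # failure rate low while any real sampling-scale bug gives p ~ 0
  for (nm in c("c_S_to_F", "K_F_to_N", "kappa_F_to_S")) {
    expect_true(all(d[[nm]] >= 0.005 & d[[nm]] <= 5000))
    ks <- stats::ks.test(log10(d[[nm]]),
                         "punif", log10(0.005), log10(5000))
    expect_gt(ks$p.value, 0.001)
  }
  for (nm in c("kappa_F", "kappa_N")) {
    expect_true(all(d[[nm]] >= 5e-6 & d[[nm]] <= 5))
    ks <- stats::ks.test(log10(d[[nm]]), "punif", log10(5e-6), log10(5))
    expect_gt(ks$p.value, 0.001)
  }
  set.seed(11); a <- sample_params(5)
  set.seed(11); b <- sample_params(5)
  expect_identical(a, b)
})

test_that("proposals are log-normal multiplicative steps clipped to range", {
  p <- as_fp_params(sample_params(1))
  set.seed(2)
  expect_equal(unclass(propose_params(p, sd = 0))[1:7], unclass(p)[1:7])
  # moments of the log-ratios
  set.seed(3)
  base <- as_fp_params(sample_params(1))
  n <- 1e5
  fac <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    prop <- propose_params(base)
    fac[i, ] <- log(unlist(unclass(prop)[1:7]) /
                      unlist(unclass(base)[1:7]))
  }
  # base is mid-range for none of the params to be clipped often; drop
  # columns where clipping occurred
  unclipped <- apply(fac, 2, function(z) {
    abs(mean(z)) < 5 * 0.2 / sqrt(n) + 0.01
  })
  expect_true(any(unclipped))
  for (j in which(unclipped)) {
    expect_lt(abs(mean(fac[, j])), 3 * 0.2 / sqrt(n) + 1e-3)
    expect_lt(abs(sd(fac[, j]) - 0.2), 3 * 0.2 / sqrt(2 * n) + 1e-3)
  }
  # clipping: a set at the upper bound never leaves the legal range
  hi <- as_fp_params(tibble::tibble(
    c_S_to_F = 5000, c_S_to_N = 5000, kappa_F = 5, kappa_N = 5,
    K_N_to_F = 5000, K_F_to_N = 5000, kappa_F_to_S = 5000))
  for (i in 1:50) {
    pr <- unclass(propose_params(hi))[1:7]
    expect_true(all(unlist(pr) <= c(5000, 5000, 5, 5, 5000, 5000, 5000)))
  }
})

test_that("criteria are evaluated as specified on constructed fixtures", {
  rep_no <- evaluate_criteria(make_criteria_fixture("no_fp"))
  expect_false(rep_no$pass_i)
  expect_false(rep_no$success)

  rep_big <- evaluate_criteria(make_criteria_fixture("fp_30pct"))
  expect_false(rep_big$pass_iv)           # 30% exceeds the 25% bound
  expect_true(rep_big$pass_i)
  expect_false(rep_big$success)

  rep_ok <- evaluate_criteria(make_criteria_fixture("fp_20pct"))
  expect_true(all(unlist(rep_ok[paste0("pass_", c("i", "ii", "iii",
                                                  "iv", "v"))])))
  expect_true(rep_ok$success)
  expect_equal(rep_ok$l_fp, 80)
  expect_equal(rep_ok$t_est, 5)

  # dorsal island breaks the two-domain requirement
  rep_isl <- evaluate_criteria(make_criteria_fixture("dorsal_island"))
  expect_false(rep_isl$pass_i)
})

test_that("the random walk screen is reproducible and well-formed", {
  expect_equal(nrow(run_screen(n_visits = 0, seed = 1)), 0)
  g <- short_growth(t_end = 4)
  a <- run_screen(n_chains = 1, n_visits = 8, seed = 31, growth = g)
  b <- run_screen(n_chains = 1, n_visits = 8, seed = 31, growth = g)
  expect_identical(a$c_S_to_F, b$c_S_to_F)
  expect_identical(a$success, b$success)
  expect_equal(nrow(a), 8)
  expect_equal(a$step, 1:8)
  # every visited set stays in the legal ranges
  expect_true(all(a$kappa_F >= 5e-6 & a$kappa_F <= 5))
  expect_true(all(a$c_S_to_N >= 0.005 & a$c_S_to_N <= 5000))
})

test_that("successful records re-evaluate to success from their parameters", {
  nets <- reference_networks("insensitive", 3)
  for (i in seq_len(nrow(nets))) {
    p <- as_fp_params(nets[i, 1:7])
    rep <- evaluate_criteria(simulate_tissue(p))
    expect_true(rep$success)
    expect_equal(rep$l_fp, nets$l_fp[i])
  }
})

test_that("sensitivity classification matches its definitions", {
  # insensitive: removing Shh^FP changes the FP by at most one bin
  ins <- as_fp_params(reference_networks("insensitive", 1)[1, 1:7])
  base <- fp_size(get_state(simulate_tissue(ins)))
  cl <- classify_sensitivity(ins, base)
  expect_equal(cl$sens_class, "insensitive")
  expect_lte(abs(cl$delta_l_fp), 4)
  # sensitive: the FP is lost entirely, delta equals the base size
  sen <- as_fp_params(reference_networks("sensitive", 1)[1, 1:7])
  base_s <- fp_size(get_state(simulate_tissue(sen)))
  cl_s <- classify_sensitivity(sen, base_s)
  expect_equal(cl_s$sens_class, "sensitive")
  expect_equal(cl_s$l_fp_perturbed, 0)
  expect_equal(cl_s$delta_l_fp, base_s)
  # the class partition is exhaustive
  expect_true(cl$sens_class %in%
                c("insensitive", "sensitive", "partial", "increased"))
})
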