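fake_records <- function() {
  # synthetic classified screen records with known relative FP sizes
  set.seed(1)
  tibble::tibble(
    c_S_to_F = runif(60, 1, 10), c_S_to_N = runif(60, 1, 10),
    kappa_F = runif(60, 0.01, 1), kappa_N = runif(60, 0.01, 1),
    K_N_to_F = runif(60, 1, 10), K_F_to_N = runif(60, 1, 10),
    kappa_F_to_S = runif(60, 0.01, 1),
    success = rep(c(TRUE, FALSE), c(50, 10)),
    l_fp = c(rep(80, 20), rep(28, 30), rep(120, 10)),
    rel_fp = c(rep(0.20, 20), rep(0.07, 30), rep(0.30, 10)),
    a_shh = 3 * c(rep(80, 20), rep(28, 30), rep(120, 10)) + rnorm(60, 0, 1),
    L_end = 400,
    sens_class = rep(c("insensitive", "sensitive", NA), c(25, 25, 10)))
}

test_that("subset selection enforces pool size and reproducibility", {
  rec <- fake_records()
  expect_error(select_subset(rec, target_rel_fp = 0.5, n = 1),
               "0 qualifying")
  expect_error(select_subset(rec, target_rel_fp = 0.2, n = 100),
               "qualifying")
  set.seed(3); a <- select_subset(rec, 0.2, n = 5)
  set.seed(3); b <- select_subset(rec, 0.2, n = 5)
  expect_identical(a, b)
  expect_true(all(abs(a$rel_fp - 0.2) <= 0.01))
  # unsuccessful records are never selected
  expect_error(select_subset(rec, 0.30, tol = 0.001, n = 1), "qualifying")
  # class filter
  ins <- select_subset(rec, 0.2, n = 3, sens_class = "insensitive")
  expect_true(all(ins$sens_class == "insensitive"))
})

test_that("sensitivity scan uses a log-equispaced grid and no perturbation leak", {
  net <- cache_networks("insensitive", 2)
  sc <- sensitivity_scan(net, "kappa_F_to_S", n_steps = 5,
                         growth = short_growth(4))
  expect_equal(sc$multiplier[1], 0.1)
  expect_equal(sc$multiplier[5], 10)
  expect_equal(diff(log10(sc$multiplier)), rep(0.5, 4))
  # multiplier exactly 1 reproduces the baseline
  base <- vapply(net, function(p) {
    st <- get_state(simulate_tissue(p, short_growth(4)))
    fp_size(st) / st$L
  }, numeric(1))
  one <- sensitivity_scan(net, "kappa_F_to_S", n_steps = 3, from = 1,
                          to = 1, growth = short_growth(4))
  expect_equal(one$mean[1], mean(base), tolerance = 1e-12)
  expect_equal(one$n_ok[1], 2)
})

test_that("without growth the floor plate stops growing after formation", {
  net <- cache_networks("insensitive", 2)
  sw <- growth_sweep(net, kp = 0, include_exponential = FALSE,
                     record_every = 2)
  late <- dplyr::filter(sw, .data$time >= 20)
  expect_equal(max(late$l_fp_mean) - min(late$l_fp_mean), 0,
               tolerance = 1e-9)
  expect_equal(unique(sw$L), 100)
})

test_that("the amplitude-FP relation recovers a linear law without a plateau", {
  rec <- tibble::tibble(l_fp = seq(4, 100, by = 4),
                        a_shh = 2.5 * seq(4, 100, by = 4))
  fit <- amplitude_fp_relation(rec, bin_width = 20)
  expect_equal(attr(fit, "slope"), 2.5, tolerance = 1e-6)
  expect_false(attr(fit, "plateau_detected"))
  # a saturating law yields a breakpoint near the shoulder
  rec2 <- tibble::tibble(l_fp = seq(4, 200, by = 2),
                         a_shh = pmin(seq(4, 200, by = 2), 60) * 3)
  fit2 <- amplitude_fp_relation(rec2, bin_width = 20)
  expect_true(attr(fit2, "plateau_detected"))
  expect_equal(attr(fit2, "breakpoint"), 60, tolerance = 0.1)
  expect_equal(attr(fit2, "slope"), 3, tolerance = 0.05)
})

test_that("tidiers return the documented shapes", {
  traj <- make_criteria_fixture("fp_20pct")
  td <- tidy(traj)
  expect_equal(nrow(td), length(traj$time) * 100)
  expect_named(td, c("time", "L", "bin", "x", "F", "N", "S"))
  gl <- glance(traj)
  expect_equal(nrow(gl), 1)
  st <- get_state(traj)
  fit <- gradient_fit(st)
  expect_named(tidy(fit), c("term", "estimate"))
  expect_equal(glance(fit)$lambda_shh, fit$lambda_shh)
})

test_that("autoplot methods return ggplot objects", {
  traj <- make_criteria_fixture("fp_20pct")
  expect_s3_class(autoplot(traj), "ggplot")
  st <- get_state(traj)
  expect_s3_class(autoplot(gradient_fit(st), st), "ggplot")
})
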