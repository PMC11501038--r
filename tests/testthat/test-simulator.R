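test_that("initial state matches the stated initial conditions", {
  p <- generic_params()
  st <- initial_state(p, growth_schedule(), source_config("pulse"))
  expect_equal(st$S[1], 100)
  expect_equal(st$S[-1], rep(0, 99))
  expect_equal(st$N, rep(10, 100))
  expect_equal(sum(st$F), 0)
  expect_equal(st$L, 100)
  st2 <- initial_state(p, growth_schedule(),
                       source_config("flux", j_shh = 1))
  expect_equal(st2$S, rep(0, 100))
})

test_that("rhs reduces to pure dilution when reactions are off", {
  p <- degenerate_params()
  g <- growth_schedule("linear")
  st <- initial_state(p, g, source_config("pulse"))
  st$F <- runif(100); st$N <- runif(100); st$S <- runif(100)
  d <- tissue_rhs(st, p, g, source_config("pulse"))
  dil <- tissue_growth_rate(g, 0) / tissue_length(g, 0)
  expect_equal(d$dF, -dil * st$F)
  expect_equal(d$dN, -dil * st$N)
  expect_equal(d$dS, -dil * st$S)
  # no growth: the dilution term vanishes
  g0 <- growth_schedule("none")
  d0 <- tissue_rhs(st, p, g0, source_config("pulse"))
  expect_equal(d0$dF, rep(0, 100))
  expect_equal(d0$dS, rep(0, 100))
})

test_that("discrete Laplacian matches a hand-computed 3-point stencil", {
  p <- degenerate_params(D_S = 396)
  g <- growth_schedule("none", L0 = 200)
  st <- initial_state(p, g, source_config("pulse", S_init = 0))
  st$S[11] <- 5                       # interior spike
  d <- tissue_rhs(st, p, g, source_config("pulse", S_init = 0))
  dc <- 396 / (200 * 0.01)^2          # D / (L dxbar)^2
  expect_equal(d$dS[10], dc * (0 - 0 + 5))
  expect_equal(d$dS[11], dc * (0 - 2 * 5 + 0))
  expect_equal(d$dS[12], dc * (5 - 0 + 0))
  expect_equal(d$dS[13], 0)
  # reflective ends: a spike in bin 1 loses mass only through one face
  st$S <- rep(0, 100); st$S[1] <- 3
  d <- tissue_rhs(st, p, g, source_config("pulse", S_init = 0))
  expect_equal(d$dS[1], dc * (0 - 3))
  expect_equal(d$dS[2], dc * (3 - 0))
})

test_that("one Heun step is exact on the linear decay system", {
  gamma <- 0.72
  p <- degenerate_params(alpha = 0, gamma = gamma, D_S = 0)
  g <- growth_schedule("none")
  st <- initial_state(p, g, source_config("pulse", S_init = 100))
  st$N <- rep(10, 100)
  dt <- 0.05
  out <- heun_step(st, dt, p, g, source_config("pulse", S_init = 100))
  fac <- 1 - gamma * dt + gamma^2 * dt^2 / 2
  expect_equal(out$S, st$S * fac, tolerance = 1e-14)
  expect_equal(out$N, st$N * fac, tolerance = 1e-14)
})

test_that("the R reference step agrees with the compiled integrator", {
  p <- generic_params()
  g <- growth_schedule()
  src <- source_config("pulse")
  dt <- 4e-4
  one <- simulate_tissue(p, growth_schedule(t_end = dt), src,
                         dt = dt, record_every = dt)
  st <- heun_step(initial_state(p, g, src), dt, p, g, src)
  expect_equal(get_state(one)$F, st$F, tolerance = 1e-12)
  expect_equal(get_state(one)$N, st$N, tolerance = 1e-12)
  expect_equal(get_state(one)$S, st$S, tolerance = 1e-12)
})

test_that("heun_step rejects steps above the diffusive stability bound", {
  p <- generic_params()   # D_S = 396, dx0 = 1 um -> bound ~1.26e-3 h
  g <- growth_schedule()
  st <- initial_state(p, g, source_config())
  expect_error(heun_step(st, 0.01, p, g, source_config()), "stability")
  expect_error(simulate_tissue(p, dt = 0.01), "stability")
})

test_that("deterministic runs are bit-identical and order-2 convergent", {
  p <- generic_params()
  g <- short_growth(t_end = 0.2)
  a <- simulate_tissue(p, g, record_every = 0.1)
  b <- simulate_tissue(p, g, record_every = 0.1)
  expect_identical(a$S, b$S)
  expect_identical(a$F, b$F)

  # global error vs a fine reference should drop ~4x when dt is halved
  dt0 <- 4e-4
  ref <- simulate_tissue(p, g, dt = dt0 / 8, record_every = 0.2)
  err <- vapply(c(dt0, dt0 / 2), function(h) {
    s <- simulate_tissue(p, g, dt = h, record_every = 0.2)
    max(abs(get_state(s)$S - get_state(ref)$S))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.5)
})

test_that("pure dilution conserves total amount in every growth mode", {
  p <- degenerate_params()
  for (mode in c("linear", "exponential")) {
    g <- growth_schedule(mode, t_end = 60)
    traj <- simulate_tissue(p, g, source_config("pulse", S_init = 100),
                            dt = 5e-3, record_every = 10)
    total <- traj$L * colMeans(traj$S)
    expect_equal(max(abs(total / total[1] - 1)), 0, tolerance = 1e-6)
  }
})

test_that("a constant flux builds the closed-form steady gradient", {
  # static domain, no FP production: S'' D - gamma S = 0 with influx Phi
  p <- degenerate_params(alpha = 0, gamma = 0.72, D_S = 396)
  g <- growth_schedule("none", L0 = 400, t_end = 30)
  j <- 0.1
  traj <- simulate_tissue(p, g, source_config("flux", j_shh = j))
  st <- get_state(traj)
  lam <- decay_length(396, 0.72)
  Phi <- 7200 * j   # centered-difference ghost: net influx 2*3600*j
  x <- (seq_len(100) - 0.5) * 400 / 100    # bin centres
  theory <- (Phi * lam / 396) *
    cosh((400 - x) / lam) / sinh(400 / lam)
  expect_equal(st$S[1], theory[1], tolerance = 0.01)
  expect_equal(st$S, theory, tolerance = 0.01)
  # the fitted decay length matches sqrt(D/gamma) within 2%
  st$N <- rep(10, 100); st$F <- rep(0, 100)
  expect_equal(gradient_fit(st)$lambda_shh, lam, tolerance = 0.02)
})

test_that("flux removal switches to reflective boundaries", {
  p <- degenerate_params(alpha = 0, gamma = 0.72, D_S = 396)
  g <- growth_schedule("none", L0 = 100, t_end = 20)
  off <- simulate_tissue(p, g,
                         source_config("flux_off", j_shh = 1, t_off = 5))
  m <- trajectory_metrics(off)
  a_at <- function(t) m$a_shh[which.min(abs(m$time - t))]
  # amplitude rises while the flux is on, then decays
  expect_gt(a_at(5), a_at(1))
  expect_lt(a_at(20), 1e-2 * a_at(5))
})

test_that("the exact OU update has the stated moments", {
  expect_equal(ou_step(2, 1, sigma_eta = 0, tau_eta = 1),
               2 * exp(-1))
  set.seed(99)
  # stationary variance sigma^2/tau and lag autocorrelation exp(-dt/tau)
  n <- 1e5; dt <- 0.1; tau <- 1; sigma <- 1
  eta <- numeric(n)
  for (i in 2:n) eta[i] <- ou_step(eta[i - 1], dt, sigma, tau)
  eta <- eta[-(1:100)]
  rho <- exp(-dt / tau)
  neff <- length(eta) * (1 - rho) / (1 + rho)
  v <- stats::var(eta)
  expect_lt(abs(v - sigma^2 / tau), 3 * sqrt(2 / neff) * sigma^2 / tau)
  ac <- stats::cor(eta[-1], eta[-length(eta)])
  expect_lt(abs(ac - rho), 3 / sqrt(neff))
})

test_that("noisy runs are reproducible under a fixed seed and stay non-negative", {
  p <- generic_params()
  nz <- noise_config(TRUE, sigma_eta = 1, tau_eta = 1)
  g <- short_growth(t_end = 1)
  set.seed(7)
  a <- simulate_tissue(p, g, noise = nz, record_every = 0.5)
  set.seed(7)
  b <- simulate_tissue(p, g, noise = nz, record_every = 0.5)
  expect_identical(a$F, b$F)
  set.seed(8)
  c_ <- simulate_tissue(p, g, noise = nz, record_every = 0.5)
  expect_false(identical(a$F, c_$F))
  expect_true(all(a$F >= 0) && all(a$N >= 0) && all(a$S >= 0))
})

test_that("trajectories report non-negative fields and aligned recording", {
  p <- generic_params()
  traj <- simulate_tissue(p, short_growth(t_end = 1), record_every = 1 / 6)
  expect_true(all(traj$F >= 0) && all(traj$N >= 0) && all(traj$S >= 0))
  expect_equal(traj$time[1], 0)
  expect_equal(max(traj$time), 1)
  expect_true(all(diff(traj$time) > 0))
  expect_equal(ncol(traj$S), length(traj$time))
})
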