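#' Initial tissue state
#'
#' Builds the state at t = 0: N expressed uniformly at 10 a.u., no F, and
#' Shh either as a concentration pulse `S_init` in the ventral-most bin
#' (pulse mode) or absent (flux modes).
#'
#' @param p An [fp_params()] object.
#' @param growth An [growth_schedule()] object.
#' @param source A [source_config()] object.
#' @param n_bins Number of spatial bins on the unit interval.
#' @return An object of class `fp_state`: a list with fields `t`, `L` and
#'   concentration vectors `F`, `N`, `S` (one value per bin).
#' @export
initial_state <- function(p, growth = growth_schedule(),
                          source = source_config(), n_bins = 100) {
  stopifnot(inherits(p, "fp_params"), inherits(growth, "fp_growth"),
            inherits(source, "fp_source"), n_bins >= 3)
  S <- rep(0, n_bins)
  if (source$mode == "pulse") S[1] <- source$S_init
  structure(list(t = 0, L = growth$L0, F = rep(0, n_bins),
                 N = rep(10, n_bins), S = S),
            class = "fp_state")
}

new_fp_state <- function(t, L, F, N, S) {
  structure(list(t = t, L = L, F = F, N = N, S = S), class = "fp_state")
}

#' @export
print.fp_state <- function(x, ...) {
  cat(sprintf("<fp_state> t=%.3g h, L=%.4g um, %d bins\n",
              x$t, x$L, length(x$F)))
  cat(sprintf("  F: [%.3g, %.3g]  N: [%.3g, %.3g]  S: [%.3g, %.3g]\n",
              min(x$F), max(x$F), min(x$N), max(x$N), min(x$S), max(x$S)))
  invisible(x)
}

# boundary influx (a.u. um / h) through the ventral face at time t;
# the centered-difference ghost closure doubles the nominal conversion
.influx <- function(source, t) {
  if (source$mode == "flux") return(7200 * source$j_shh)
  if (source$mode == "flux_off" && t < source$t_off)
    return(7200 * source$j_shh)
  0
}

#' Right-hand side of the growing-domain model
#'
#' Reference (pure R) evaluation of the time derivatives of F, N and Shh
#' in mapped coordinates: reaction terms, discrete diffusion of Shh with
#' the boundary closure of the active source configuration, and the
#' dilution term -c * Ldot / L that arises from uniform domain growth.
#' The compiled integrator used by [simulate_tissue()] evaluates the same
#' expressions; this function exists for inspection and testing.
#'
#' @param state An `fp_state`.
#' @inheritParams initial_state
#' @return A list with numeric vectors `dF`, `dN`, `dS` (a.u. per hour).
#' @export
tissue_rhs <- function(state, p, growth = growth_schedule(),
                       source = source_config()) {
  stopifnot(inherits(state, "fp_state"))
  n <- length(state$F)
  Fv <- state$F; Nv <- state$N; Sv <- state$S
  L <- tissue_length(growth, state$t)
  dil <- tissue_growth_rate(growth, state$t) / L
  dxb <- 1 / n
  dF <- reaction_rate_F(Fv, Nv, Sv, p) - dil * Fv
  dN <- reaction_rate_N(Fv, Nv, Sv, p) - dil * Nv
  dc <- p$D_S / (L * dxb)^2
  lap <- c(dc * (Sv[2] - Sv[1]) + .influx(source, state$t) / (L * dxb),
           dc * (Sv[3:n] + Sv[seq_len(n - 2)] - 2 * Sv[2:(n - 1)]),
           dc * (Sv[n - 1] - Sv[n]))
  dS <- lap + shh_production(Fv, p) - p$gamma_S * Sv - dil * Sv
  list(dF = dF, dN = dN, dS = dS)
}

#' One Heun (predictor-corrector) step
#'
#' Advances an `fp_state` by `dt` using the second-order Heun scheme:
#' an Euler predictor followed by a trapezoidal corrector. If a noise
#' configuration is supplied, Ornstein--Uhlenbeck increments are applied
#' to F and N after the deterministic update (only in bins above the
#' noise threshold) and concentrations are clamped at zero.
#'
#' @param state An `fp_state`. When noise is enabled the state carries
#'   the OU variables `eta_F`, `eta_N` (initialized to zero if absent).
#' @param dt Time step, hours. Must not exceed the diffusive stability
#'   bound (L0 / n_bins)^2 / (2 D_S).
#' @inheritParams initial_state
#' @param noise A [noise_config()] or `NULL`.
#' @return The advanced `fp_state`.
#' @export
heun_step <- function(state, dt, p, growth = growth_schedule(),
                      source = source_config(), noise = NULL) {
  stopifnot(dt > 0)
  dx0 <- growth$L0 / length(state$F)
  if (dt > dx0^2 / (2 * p$D_S))
    stop(sprintf(
      "dt = %.3g h exceeds the diffusive stability bound %.3g h",
      dt, dx0^2 / (2 * p$D_S)), call. = FALSE)
  k1 <- tissue_rhs(state, p, growth, source)
  pred <- new_fp_state(state$t + dt, tissue_length(growth, state$t + dt),
                       state$F + dt * k1$dF, state$N + dt * k1$dN,
                       state$S + dt * k1$dS)
  k2 <- tissue_rhs(pred, p, growth, source)
  Fv <- state$F + dt / 2 * (k1$dF + k2$dF)
  Nv <- state$N + dt / 2 * (k1$dN + k2$dN)
  Sv <- state$S + dt / 2 * (k1$dS + k2$dS)
  out <- new_fp_state(state$t + dt, pred$L, Fv, Nv, Sv)
  if (!is.null(noise) && noise$enabled) {
    etaF <- state$eta_F %||% rep(0, length(Fv))
    etaN <- state$eta_N %||% rep(0, length(Nv))
    etaF <- ou_step(etaF, dt, noise$sigma_eta, noise$tau_eta)
    etaN <- ou_step(etaN, dt, noise$sigma_eta, noise$tau_eta)
    out$F <- ifelse(Fv > noise$threshold, Fv + etaF * dt, Fv)
    out$N <- ifelse(Nv > noise$threshold, Nv + etaN * dt, Nv)
    out$eta_F <- etaF
    out$eta_N <- etaN
  }
  out$F <- pmax(out$F, 0)
  out$N <- pmax(out$N, 0)
  out$S <- pmax(out$S, 0)
  out
}

#' Exact Ornstein--Uhlenbeck update
#'
#' Advances an OU variable eta over a step `dt` using the exact
#' discretization
#' `eta' = eta * exp(-dt/tau) + sigma * sqrt((1 - exp(-2 dt/tau)) / tau) * z`
#' with z ~ N(0, 1). The stationary standard deviation is
#' `sigma / sqrt(tau)`.
#'
#' @param eta Current value(s) of the OU variable.
#' @param dt Time step, hours.
#' @param sigma_eta Noise magnitude.
#' @param tau_eta Correlation time, hours.
#' @return Updated value(s), same length as `eta`.
#' @export
ou_step <- function(eta, dt, sigma_eta, tau_eta) {
  stopifnot(dt > 0, tau_eta > 0, sigma_eta >= 0)
  decay <- exp(-dt / tau_eta)
  sd_inc <- sigma_eta * sqrt((1 - exp(-2 * dt / tau_eta)) / tau_eta)
  eta * decay + sd_inc * stats::rnorm(length(eta))
}

.default_dt <- function(p, growth, n_bins) {
  0.4 * (growth$L0 / n_bins)^2 / (2 * p$D_S)
}

#' Simulate the growing neural-tube model
#'
#' Integrates the three-species reaction-diffusion system from t = 0 to
#' `growth$t_end` with the Heun scheme on 100 spatial bins (mapped
#' coordinates), recording snapshots at a fixed cadence. The integration
#' itself runs in compiled code.
#'
#' By default the time step adapts to the diffusive stability limit of
#' the explicit scheme: dt(t) = 0.4 (L(t)/n_bins)^2 / (2 D_S), i.e. forty
#' percent of the stability bound at the current tissue length (about
#' 1.8 s at L = 100 um, growing as the domain -- and with it the bin
#' width -- expands). Passing an explicit `dt` instead uses that fixed
#' step throughout; it must respect the bound at the initial (stiffest)
#' length. Steps are clipped so snapshots land exactly on the recording
#' grid.
#'
#' @inheritParams initial_state
#' @param noise A [noise_config()] or `NULL` for deterministic dynamics.
#'   Noise draws use R's RNG, so runs are reproducible under `set.seed()`.
#' @param dt Fixed time step, hours; `NULL` (default) for
#'   stability-bounded adaptive stepping.
#' @param record_every Snapshot recording interval, hours (default 10
#'   min).
#' @return An object of class `fp_trajectory`: recorded times, lengths,
#'   concentration matrices (`n_bins` x n snapshots) and the
#'   configuration used. The establishment time (first recorded time with
#'   F > N in the ventral-most bin) is stored as `t_est`.
#' @seealso [trajectory_metrics()], [fp_size()], [gradient_fit()]
#' @export
#' @examples
#' p <- fp_params(
#'   c_S_to_F = 0.5, c_S_to_N = 50, kappa_F = 0.3, kappa_N = 0.02,
#'   K_N_to_F = 1, K_F_to_N = 2, kappa_F_to_S = 0.02
#' )
#' traj <- simulate_tissue(p)
#' traj
simulate_tissue <- function(p, growth = growth_schedule(),
                            source = source_config(), noise = NULL,
                            dt = NULL, record_every = 1 / 6,
                            n_bins = 100) {
  stopifnot(inherits(p, "fp_params"), inherits(growth, "fp_growth"),
            inherits(source, "fp_source"))
  if (is.null(dt)) {
    if (p$D_S <= 0)
      stop("`dt` must be supplied explicitly when D_S = 0", call. = FALSE)
    dt <- -1  # adaptive stepping in the compiled core
  } else {
    dx0 <- growth$L0 / n_bins
    if (p$D_S > 0 && dt > dx0^2 / (2 * p$D_S))
      stop(sprintf(
        "dt = %.3g h exceeds the diffusive stability bound %.3g h",
        dt, dx0^2 / (2 * p$D_S)), call. = FALSE)
    stopifnot(dt > 0)
  }
  stopifnot(record_every > 0)
  noise_on <- !is.null(noise) && isTRUE(noise$enabled)
  gmode <- match(growth$mode, c("none", "linear", "exponential")) - 1L
  smode <- match(source$mode, c("pulse", "flux", "flux_off")) - 1L
  res <- .sim_core(
    unlist(p[c(.screen_param_names, "alpha_F", "alpha_N", "alpha_S",
               "gamma_F", "gamma_N", "gamma_S", "D_S",
               "m_N_to_F", "m_F_to_N")], use.names = FALSE),
    gmode, growth$L0, growth$k_p, growth$tau, growth$t_end,
    smode, source$S_init, source$j_shh,
    ifelse(is.na(source$t_off), -1, source$t_off),
    noise_on,
    if (noise_on) noise$sigma_eta else 0,
    if (noise_on) noise$tau_eta else 1,
    if (noise_on) noise$threshold else 1,
    dt, record_every, as.integer(n_bins))
  structure(list(time = as.numeric(res$time), L = as.numeric(res$L),
                 F = res$F, N = res$N, S = res$S,
                 t_est = res$t_est, dt = res$dt, n_bins = n_bins,
                 params = p, growth = growth, source = source,
                 noise = if (noise_on) noise else NULL),
            class = "fp_trajectory")
}

#' @export
print.fp_trajectory <- function(x, ...) {
  nt <- length(x$time)
  st <- get_state(x, nt)
  cat(sprintf(
    "<fp_trajectory> %d snapshots, t in [0, %g] h, L: %g -> %g um\n",
    nt, max(x$time), x$L[1], x$L[nt]))
  cat(sprintf("  source=%s, growth=%s, noise=%s\n",
              x$source$mode, x$growth$mode,
              ifelse(is.null(x$noise), "off", "on")))
  cat(sprintf("  final: l_FP=%.3g um (%.1f%% of L), A_Shh=%.4g a.u., T_est=%s h\n",
              fp_size(st), 100 * fp_size(st) / st$L, st$S[1],
              ifelse(is.na(x$t_est), "-", format(x$t_est))))
  invisible(x)
}

#' Extract one recorded snapshot from a trajectory
#'
#' @param traj An `fp_trajectory`.
#' @param which Snapshot index, or a time in hours via `t`. Defaults to
#'   the final snapshot.
#' @param t Time, hours; the nearest recorded snapshot is returned.
#' @return An `fp_state`.
#' @export
get_state <- function(traj, which = NULL, t = NULL) {
  stopifnot(inherits(traj, "fp_trajectory"))
  if (is.null(which)) {
    which <- if (is.null(t)) length(traj$time)
             else which.min(abs(traj$time - t))
  }
  new_fp_state(traj$time[which], traj$L[which],
               traj$F[, which], traj$N[, which], traj$S[, which])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
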