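#' Model parameter set for the three-species floor-plate network
#'
#' Bundles the seven screened interaction parameters of the
#' floor-plate / neural-progenitor / Shh network together with the fixed
#' production, degradation, diffusion and cooperativity constants. All
#' rates are stored in hour units; the defaults correspond to production
#' rates of 0.1 a.u. per second (360 a.u. h^-1), degradation rates of
#' 2e-4 s^-1 (0.72 h^-1) and a Shh diffusion coefficient of
#' 0.11 um^2 s^-1 (396 um^2 h^-1).
#'
#' The interaction parameters have no defaults: they are the quantities
#' explored by the computational screen (see [run_screen()]).
#'
#' @param c_S_to_F,c_S_to_N Activation strength of F (resp. N) by Shh,
#'   relative to uniform activation (dimensionless; screened over
#'   0.005--5000).
#' @param kappa_F,kappa_N Uniform (basal) activation constants
#'   (dimensionless; screened over 5e-6--5).
#' @param K_N_to_F,K_F_to_N Repressor binding affinities of N on F and of
#'   F on N (per a.u.; screened over 0.005--5000).
#' @param kappa_F_to_S Activation strength of Shh production by the floor
#'   plate (per a.u.; screened over 0.005--5000). May be exactly 0, which
#'   switches floor-plate-derived Shh off.
#' @param alpha_F,alpha_N,alpha_S Production rates, a.u. per hour.
#' @param gamma_F,gamma_N,gamma_S Degradation rates, per hour.
#' @param D_S Shh diffusion coefficient, um^2 per hour.
#' @param m_N_to_F,m_F_to_N Repression cooperativity exponents (>= 1).
#'
#' @return An object of class `fp_params` (a named list).
#' @seealso [reaction_rate_F()], [simulate_tissue()], [sample_params()]
#' @export
#' @examples
#' p <- fp_params(
#'   c_S_to_F = 1, c_S_to_N = 1, kappa_F = 0.05, kappa_N = 0.5,
#'   K_N_to_F = 5, K_F_to_N = 5, kappa_F_to_S = 0.05
#' )
#' p
fp_params <- function(c_S_to_F, c_S_to_N, kappa_F, kappa_N,
                      K_N_to_F, K_F_to_N, kappa_F_to_S,
                      alpha_F = 360, alpha_N = 360, alpha_S = 360,
                      gamma_F = 0.72, gamma_N = 0.72, gamma_S = 0.72,
                      D_S = 396, m_N_to_F = 3, m_F_to_N = 3) {
  p <- list(
    c_S_to_F = c_S_to_F, c_S_to_N = c_S_to_N,
    kappa_F = kappa_F, kappa_N = kappa_N,
    K_N_to_F = K_N_to_F, K_F_to_N = K_F_to_N,
    kappa_F_to_S = kappa_F_to_S,
    alpha_F = alpha_F, alpha_N = alpha_N, alpha_S = alpha_S,
    gamma_F = gamma_F, gamma_N = gamma_N, gamma_S = gamma_S,
    D_S = D_S, m_N_to_F = m_N_to_F, m_F_to_N = m_F_to_N
  )
  validate_fp_params(p)
  structure(p, class = "fp_params")
}

validate_fp_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    v
  }
  for (nm in names(p)) num1(nm)
  pos <- c("c_S_to_F", "c_S_to_N", "kappa_F", "kappa_N", "K_N_to_F",
           "K_F_to_N")
  for (nm in pos) {
    if (p[[nm]] <= 0)
      stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  # rates may be zeroed for degenerate test systems (pure dilution etc.)
  nonneg <- c("kappa_F_to_S", "alpha_F", "alpha_N", "alpha_S",
              "gamma_F", "gamma_N", "gamma_S", "D_S")
  for (nm in nonneg) {
    if (p[[nm]] < 0)
      stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  if (p$m_N_to_F < 1 || p$m_F_to_N < 1)
    stop("repression exponents must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.fp_params <- function(x, ...) {
  cat("<fp_params>\n")
  cat("  screened:",
      paste(sprintf("%s=%.4g", names(x)[1:7], unlist(x[1:7])),
            collapse = ", "), "\n")
  cat("  fixed:   ",
      sprintf("alpha=%.4g/%.4g/%.4g a.u./h, gamma=%.3g/%.3g/%.3g /h",
              x$alpha_F, x$alpha_N, x$alpha_S,
              x$gamma_F, x$gamma_N, x$gamma_S), "\n")
  cat("           ",
      sprintf("D_S=%.4g um^2/h, m=%g/%g",
              x$D_S, x$m_N_to_F, x$m_F_to_N), "\n")
  invisible(x)
}

.screen_param_names <- c("c_S_to_F", "c_S_to_N", "kappa_F", "kappa_N",
                         "K_N_to_F", "K_F_to_N", "kappa_F_to_S")

.screen_ranges <- function() {
  lo <- c(c_S_to_F = 0.005, c_S_to_N = 0.005, kappa_F = 5e-6,
          kappa_N = 5e-6, K_N_to_F = 0.005, K_F_to_N = 0.005,
          kappa_F_to_S = 0.005)
  hi <- c(c_S_to_F = 5000, c_S_to_N = 5000, kappa_F = 5,
          kappa_N = 5, K_N_to_F = 5000, K_F_to_N = 5000,
          kappa_F_to_S = 5000)
  list(lo = lo, hi = hi)
}

#' Coerce to a model parameter set
#'
#' Converts a named list, a one-row data frame (for instance a row of the
#' tibble returned by [run_screen()] or [sample_params()]) or an
#' `fp_params` object into an `fp_params` object. Missing fixed rates are
#' filled with the package defaults (see [fp_params()]).
#'
#' @param x Object carrying at least the seven screened parameters.
#' @param ... Overrides passed on to [fp_params()] (e.g.
#'   `kappa_F_to_S = 0` to switch floor-plate-derived Shh off).
#' @return An `fp_params` object.
#' @export
as_fp_params <- function(x, ...) {
  if (inherits(x, "fp_params") && !length(list(...))) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- unclass(x)
  keep <- intersect(names(formals(fp_params)), names(x))
  args <- utils::modifyList(x[keep], list(...))
  do.call(fp_params, args)
}

#' Serialize a parameter set to JSON
#'
#' Writes (or returns) a flat JSON object with one key per field of
#' [fp_params()], including the fixed rates, so that runs are
#' self-describing.
#'
#' @param p An `fp_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
params_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "fp_params"))
  js <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path File path or JSON string produced by [params_to_json()].
#' @return An `fp_params` object.
#' @export
params_from_json <- function(path) {
  as_fp_params(jsonlite::fromJSON(path))
}

#' Growth schedule of the one-dimensional tissue
#'
#' Describes the deterministic growth of the dorsoventral (DV) axis. The
#' default linear schedule grows the tissue from 100 um to 400 um over
#' 60 h at 5 um/h; the exponential mode uses L(t) = L0 exp(t / tau).
#'
#' @param mode Growth mode: `"linear"`, `"none"` or `"exponential"`.
#' @param L0 Initial DV length, um.
#' @param k_p Linear growth rate, um per hour.
#' @param tau Exponential growth time constant, hours.
#' @param t_end Simulation end time, hours.
#' @return An object of class `fp_growth`.
#' @export
#' @examples
#' g <- growth_schedule()
#' tissue_length(g, c(0, 30, 60))
growth_schedule <- function(mode = c("linear", "none", "exponential"),
                            L0 = 100, k_p = 5, tau = 43.3, t_end = 60) {
  mode <- match.arg(mode)
  stopifnot(L0 > 0, t_end > 0, tau > 0, k_p >= 0)
  structure(list(mode = mode, L0 = L0, k_p = k_p, tau = tau, t_end = t_end),
            class = "fp_growth")
}

#' @export
print.fp_growth <- function(x, ...) {
  cat(sprintf("<fp_growth> %s: L0=%g um, t_end=%g h, L_end=%g um\n",
              x$mode, x$L0, x$t_end, tissue_length(x, x$t_end)))
  invisible(x)
}

#' Tissue length and growth rate
#'
#' @param g An `fp_growth` schedule.
#' @param t Time(s), hours.
#' @return `tissue_length()`: L(t) in um. `tissue_growth_rate()`: dL/dt in
#'   um per hour.
#' @export
tissue_length <- function(g, t) {
  stopifnot(inherits(g, "fp_growth"))
  switch(g$mode,
         none = rep(g$L0, length(t)),
         linear = g$L0 + g$k_p * t,
         exponential = g$L0 * exp(t / g$tau))
}

#' @rdname tissue_length
#' @export
tissue_growth_rate <- function(g, t) {
  stopifnot(inherits(g, "fp_growth"))
  switch(g$mode,
         none = rep(0, length(t)),
         linear = rep(g$k_p, length(t)),
         exponential = (g$L0 / g$tau) * exp(t / g$tau))
}

#' Shh source configuration
#'
#' Describes how notochord-derived Shh enters the tissue: as a transient
#' concentration pulse in the ventral-most bin at t = 0 (`"pulse"`), as a
#' constant boundary flux through the ventral end (`"flux"`), or as a flux
#' that is abruptly removed at `t_off` (`"flux_off"`), after which both
#' boundaries are reflective.
#'
#' The flux magnitude `j_shh` is given in the units used throughout the
#' figures, a.u. per second. The flux condition is imposed through a
#' mirrored (centered-difference) ghost bin, so the net influx through
#' the ventral face is `2 * 3600 * j_shh` a.u. um per hour; this is the
#' calibration under which the amplitude-flux relation reproduces the
#' reported flux contributions, and it is verified against the
#' closed-form steady-state gradient in the test suite.
#'
#' @param mode `"pulse"`, `"flux"` or `"flux_off"`.
#' @param S_init Pulse magnitude, a.u. (pulse mode only).
#' @param j_shh Boundary flux magnitude, a.u. per second (flux modes).
#' @param t_off Flux removal time, hours (flux_off mode only).
#' @return An object of class `fp_source`.
#' @export
source_config <- function(mode = c("pulse", "flux", "flux_off"),
                          S_init = 100, j_shh = 0, t_off = NULL) {
  mode <- match.arg(mode)
  if (mode == "pulse") {
    stopifnot(S_init >= 0)
    j_shh <- 0
    t_off <- NA_real_
  } else {
    stopifnot(j_shh >= 0)
    S_init <- 0
    if (mode == "flux_off") {
      if (is.null(t_off) || !is.finite(t_off) || t_off <= 0)
        stop("`t_off` must be a positive time (hours) in flux_off mode",
             call. = FALSE)
    } else {
      t_off <- NA_real_
    }
  }
  structure(list(mode = mode, S_init = S_init, j_shh = j_shh,
                 t_off = as.numeric(t_off)),
            class = "fp_source")
}

#' @export
print.fp_source <- function(x, ...) {
  cat(sprintf("<fp_source> %s: S_init=%g a.u., j_shh=%g a.u./s, t_off=%s h\n",
              x$mode, x$S_init, x$j_shh,
              ifelse(is.na(x$t_off), "-", format(x$t_off))))
  invisible(x)
}

#' Ornstein--Uhlenbeck expression-noise configuration
#'
#' Fluctuations in F and N expression (a proxy for stochastic effects of
#' cell division) are modelled as an Ornstein--Uhlenbeck process added to
#' the deterministic dynamics, applied only in bins where the respective
#' expression level exceeds `threshold`. With the defaults
#' (`sigma_eta = 1`, `tau_eta = 1`) the stationary standard deviation of
#' the noise term, `sigma_eta / sqrt(tau_eta)`, is 1 a.u.
#'
#' @param enabled Logical; switch noise on or off.
#' @param sigma_eta Noise magnitude (a.u. h^-1/2 under the exact
#'   discretization used by [ou_step()]).
#' @param tau_eta Noise correlation time, hours.
#' @param threshold Expression floor (a.u.) below which noise is not
#'   applied.
#' @return An object of class `fp_noise`.
#' @export
noise_config <- function(enabled = TRUE, sigma_eta = 1, tau_eta = 1,
                         threshold = 1) {
  stopifnot(is.logical(enabled), sigma_eta >= 0, tau_eta > 0)
  structure(list(enabled = enabled, sigma_eta = sigma_eta,
                 tau_eta = tau_eta, threshold = threshold),
            class = "fp_noise")
}

#' Regulatory production-degradation rate of the floor-plate factor F
#'
#' Net rate of change of F (excluding dilution) under the thermodynamic
#' activation/repression model: Shh and a uniform basal input activate F,
#' N represses it cooperatively.
#'
#' @param F,N,S Concentrations, a.u. (non-negative; vectorized).
#' @param p An [fp_params()] object.
#' @return Rate of change of F, a.u. per hour.
#' @export
#' @examples
#' p <- fp_params(1, 1, 1, 1, 1, 1, 1, alpha_F = 0.1)
#' reaction_rate_F(0, 0, 0, p)  # 0.05
reaction_rate_F <- function(F, N, S, p) {
  stopifnot(inherits(p, "fp_params"))
  if (any(F < 0) || any(N < 0) || any(S < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  act <- p$kappa_F * (1 + p$c_S_to_F * S)
  rep_ <- (1 + p$K_N_to_F * N)^p$m_N_to_F
  p$alpha_F * act / (rep_ + act) - p$gamma_F * F
}

#' Regulatory production-degradation rate of the progenitor factor N
#'
#' Mirror image of [reaction_rate_F()]: Shh and a basal input activate N,
#' F represses it cooperatively.
#'
#' @inheritParams reaction_rate_F
#' @return Rate of change of N, a.u. per hour.
#' @export
reaction_rate_N <- function(F, N, S, p) {
  stopifnot(inherits(p, "fp_params"))
  if (any(F < 0) || any(N < 0) || any(S < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  act <- p$kappa_N * (1 + p$c_S_to_N * S)
  rep_ <- (1 + p$K_F_to_N * F)^p$m_F_to_N
  p$alpha_N * act / (rep_ + act) - p$gamma_N * N
}

#' Shh production by the floor plate
#'
#' Saturating production of Shh as a function of the floor-plate factor F.
#' No Shh is produced if F = 0 or if `kappa_F_to_S` = 0.
#'
#' @inheritParams reaction_rate_F
#' @return Shh production rate, a.u. per hour (degradation not included).
#' @export
shh_production <- function(F, p) {
  stopifnot(inherits(p, "fp_params"))
  if (any(F < 0)) stop("concentrations must be non-negative", call. = FALSE)
  h <- p$kappa_F_to_S * F
  p$alpha_S * h / (1 + h)
}

#' Steady-state decay length of an exponential morphogen gradient
#'
#' For a gradient formed by diffusion with coefficient `D`, uniform
#' degradation at rate `gamma` and localized production, the steady-state
#' decay length is sqrt(D / gamma). `D` and `gamma` must use the same time
#' unit; with the model defaults (D_S = 0.11 um^2/s, gamma_S = 2e-4 /s,
#' equivalently 396 um^2/h and 0.72 /h) this gives 23.45 um.
#'
#' @param D Diffusion coefficient, um^2 per unit time.
#' @param gamma Degradation rate, per unit time.
#' @return Decay length, um.
#' @export
#' @examples
#' decay_length(0.11, 2e-4)  # 23.45 um
decay_length <- function(D, gamma) {
  if (any(D <= 0) || any(gamma <= 0))
    stop("`D` and `gamma` must be strictly positive", call. = FALSE)
  sqrt(D / gamma)
}
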