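#' Floor-plate size of a tissue state
#'
#' The floor plate (FP) is the maximal contiguous run of bins starting at
#' the ventral end (x = 0) in which F strictly exceeds N; ties count as
#' N. Its length is the number of such bins times the bin width L /
#' n_bins. Dorsal islands of F > N do not count.
#'
#' @param state An `fp_state`, or a list with fields `F`, `N`, `L`.
#' @return FP size, um (0 if F <= N in the ventral-most bin).
#' @export
fp_size <- function(state) {
  above <- state$F > state$N
  n_run <- match(FALSE, above, nomatch = length(above) + 1L) - 1L
  n_run * state$L / length(above)
}

.fp_bins <- function(F, N) {
  above <- F > N
  match(FALSE, above, nomatch = length(above) + 1L) - 1L
}

#' Floor-plate establishment time
#'
#' First recorded time at which F exceeds N in the ventral-most bin.
#'
#' @param traj An `fp_trajectory`.
#' @return Time in hours, or `NA` if F never exceeds N ventrally.
#' @export
establishment_time <- function(traj) {
  stopifnot(inherits(traj, "fp_trajectory"))
  if (!is.null(traj$t_est)) return(as.numeric(traj$t_est))
  idx <- which(traj$F[1, ] > traj$N[1, ])
  if (!length(idx)) return(NA_real_)
  traj$time[idx[1]]
}

#' Floor-plate formation time
#'
#' Earliest recorded time after which the relative FP size l_FP(t) / L(t)
#' stays within `tol` of its final value for all later recorded times.
#' The default tolerance of 0.01 corresponds to one spatial bin.
#'
#' @param traj An `fp_trajectory`.
#' @param tol Relative-size tolerance.
#' @return Time in hours; `NA` if no FP exists at the end of the run.
#' @export
formation_time <- function(traj, tol = 0.01) {
  stopifnot(inherits(traj, "fp_trajectory"))
  nb <- nrow(traj$F)
  rel <- vapply(seq_along(traj$time),
                function(k) .fp_bins(traj$F[, k], traj$N[, k]) / nb,
                numeric(1))
  nt <- length(rel)
  if (rel[nt] == 0) return(NA_real_)
  ok <- abs(rel - rel[nt]) <= tol + 1e-12
  # last index at which the band is violated
  bad <- which(!ok)
  if (!length(bad)) return(traj$time[1])
  if (max(bad) == nt) return(NA_real_)
  traj$time[max(bad) + 1L]
}

#' Exponential fit to the Shh gradient in the N domain
#'
#' Fits A exp(-x / lambda) to the Shh profile over the N domain (bins
#' where N > F), excluding bins with S below `floor`, by least squares
#' on the concentration scale (initialized from an amplitude-weighted
#' log-linear fit, which it falls back to if the nonlinear refinement
#' fails). Fitting on the concentration scale weights the proximal part
#' of the gradient, where the profile has reached its quasi-steady
#' exponential shape; an unweighted log fit would instead be dominated
#' by the dorsal tail, which on a growing domain is still spreading and
#' systematically shallower. The amplitude A_Shh is reported as the S
#' concentration in the ventral-most bin (the model analogue of the
#' gradient peak).
#'
#' @param state An `fp_state`.
#' @param floor Numeric floor (a.u.) below which bins are excluded from
#'   the fit.
#' @param min_bins Minimum number of usable bins; fewer raises a
#'   fit-failure error, as does a non-decaying profile.
#' @return An object of class `fp_gradient_fit` with fields `A_shh`,
#'   `lambda_shh` (um), `fit_window` (um range used), `sigma` (RMS
#'   residual of the fit, a.u.) and `n_bins_used`.
#' @export
#' @examples
#' st <- structure(list(t = 60, L = 400, F = rep(0, 100), N = rep(1, 100),
#'                      S = 100 * exp(-(1:100 - 0.5) * 4 / 23.45)),
#'                 class = "fp_state")
#' gradient_fit(st)
gradient_fit <- function(state, floor = 1e-8, min_bins = 5) {
  n <- length(state$S)
  x <- (seq_len(n) - 0.5) * state$L / n
  use <- state$N > state$F & state$S > floor
  if (sum(use) < min_bins)
    stop("gradient fit failed: fewer than ", min_bins,
         " usable bins in the N domain", call. = FALSE)
  xs <- x[use]
  S <- state$S[use]
  ys <- log(S)
  w <- S^2
  xm <- sum(w * xs) / sum(w)
  ym <- sum(w * ys) / sum(w)
  slope <- sum(w * (xs - xm) * (ys - ym)) / sum(w * (xs - xm)^2)
  if (!is.finite(slope) || slope >= 0)
    stop("gradient fit failed: Shh profile does not decay over the N domain",
         call. = FALSE)
  lam <- -1 / slope
  A0 <- exp(ym + xm / lam)
  co <- tryCatch(suppressWarnings({
    fit <- stats::nls(S ~ A * exp(-xs / l),
                      start = list(A = A0, l = lam),
                      control = stats::nls.control(warnOnly = TRUE))
    stats::coef(fit)
  }), error = function(e) c(A = A0, l = lam))
  if (!is.finite(co[["l"]]) || co[["l"]] <= 0)
    co <- c(A = A0, l = lam)
  resid <- S - co[["A"]] * exp(-xs / co[["l"]])
  structure(list(A_shh = state$S[1], lambda_shh = co[["l"]],
                 fit_window = range(xs),
                 sigma = sqrt(mean(resid^2)),
                 n_bins_used = sum(use)),
            class = "fp_gradient_fit")
}

#' @export
print.fp_gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<fp_gradient_fit> A_Shh=%.4g a.u., lambda=%.4g um (%d bins, x in [%.3g, %.3g] um)\n",
    x$A_shh, x$lambda_shh, x$n_bins_used, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Per-snapshot derived metrics of a trajectory
#'
#' Computes, for every recorded snapshot: tissue length, absolute and
#' relative FP size, Shh amplitude (ventral-most bin) and, optionally,
#' the fitted Shh decay length in the N domain (`NA` where the fit
#' fails).
#'
#' @param traj An `fp_trajectory`.
#' @param fit_lambda Logical; fit the decay length per snapshot.
#' @return A tibble with columns `time`, `L`, `l_fp`, `rel_fp`, `a_shh`
#'   and (optionally) `lambda_shh`.
#' @export
trajectory_metrics <- function(traj, fit_lambda = FALSE) {
  stopifnot(inherits(traj, "fp_trajectory"))
  nb <- nrow(traj$F)
  nt <- length(traj$time)
  l_fp <- vapply(seq_len(nt), function(k)
    .fp_bins(traj$F[, k], traj$N[, k]) * traj$L[k] / nb, numeric(1))
  out <- tibble::tibble(
    time = traj$time, L = traj$L, l_fp = l_fp,
    rel_fp = l_fp / traj$L, a_shh = traj$S[1, ])
  if (fit_lambda) {
    out$lambda_shh <- vapply(seq_len(nt), function(k) {
      tryCatch(gradient_fit(get_state(traj, k))$lambda_shh,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  out
}
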