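#' Tidy a simulated trajectory into long format
#'
#' @param x An `fp_trajectory`.
#' @param ... Ignored.
#' @return A tibble with one row per snapshot and bin: `time`, `L`,
#'   `bin`, `x` (absolute position of the bin centre, um), `F`, `N`,
#'   `S`.
#' @export
tidy.fp_trajectory <- function(x, ...) {
  nb <- nrow(x$F)
  nt <- length(x$time)
  L_rep <- rep(x$L, each = nb)
  # bind columns from precomputed vectors: the position column is named
  # `x`, which would otherwise shadow the trajectory inside tibble()
  Fv <- as.vector(x$F)
  Nv <- as.vector(x$N)
  Sv <- as.vector(x$S)
  tibble::tibble(
    time = rep(x$time, each = nb),
    L = L_rep,
    bin = rep(seq_len(nb), nt),
    x = rep(seq_len(nb) - 0.5, nt) / nb * L_rep,
    F = Fv, N = Nv, S = Sv)
}

#' One-row summary of a simulated trajectory
#'
#' @param x An `fp_trajectory`.
#' @param ... Ignored.
#' @return A one-row tibble: `t_end`, `L_end`, `l_fp`, `rel_fp`,
#'   `a_shh`, `lambda_shh` (`NA` if the gradient fit fails), `t_est`,
#'   `t_fp`.
#' @export
glance.fp_trajectory <- function(x, ...) {
  st <- get_state(x)
  tibble::tibble(
    t_end = st$t, L_end = st$L, l_fp = fp_size(st),
    rel_fp = fp_size(st) / st$L, a_shh = st$S[1],
    lambda_shh = tryCatch(gradient_fit(st)$lambda_shh,
                          error = function(e) NA_real_),
    t_est = establishment_time(x),
    t_fp = formation_time(x))
}

#' Tidy a gradient fit
#'
#' @param x An `fp_gradient_fit`.
#' @param ... Ignored.
#' @return A tibble with one row per fitted quantity (`A_shh`,
#'   `lambda_shh`) and its estimate.
#' @export
tidy.fp_gradient_fit <- function(x, ...) {
  tibble::tibble(term = c("A_shh", "lambda_shh"),
                 estimate = c(x$A_shh, x$lambda_shh))
}

#' One-row summary of a gradient fit
#'
#' @param x An `fp_gradient_fit`.
#' @param ... Ignored.
#' @return A one-row tibble: `A_shh`, `lambda_shh`, `sigma`,
#'   `n_bins_used`, `window_lo`, `window_hi`.
#' @export
glance.fp_gradient_fit <- function(x, ...) {
  tibble::tibble(A_shh = x$A_shh, lambda_shh = x$lambda_shh,
                 sigma = x$sigma, n_bins_used = x$n_bins_used,
                 window_lo = x$fit_window[1], window_hi = x$fit_window[2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
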