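#' Plot a simulated trajectory
#'
#' Shows spatial concentration profiles of F, N and Shh at a set of
#' times (in absolute coordinates, so tissue growth is visible).
#'
#' @param object An `fp_trajectory`.
#' @param times Times (h) at which to draw profiles; defaults to five
#'   snapshots spread over the run.
#' @param log_s Plot Shh on a log axis in its own panel.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_trajectory <- function(object, times = NULL, log_s = FALSE,
                                   ...) {
  times <- times %||% seq(0, max(object$time), length.out = 5)
  d <- dplyr::bind_rows(lapply(times, function(t) {
    st <- get_state(object, t = t)
    nb <- length(st$F)
    tibble::tibble(time = st$t, x = (seq_len(nb) - 0.5) * st$L / nb,
                   F = st$F, N = st$N, Shh = st$S)
  })) |>
    tidyr::pivot_longer(c("F", "N", "Shh"), names_to = "species",
                        values_to = "conc")
  gg <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$x, y = .data$conc, colour = factor(round(.data$time, 1)))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "position (µm)", y = "concentration (a.u.)",
                  colour = "time (h)") +
    ggplot2::theme_minimal()
  if (log_s) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot a sensitivity curve
#'
#' Mean observable (relative FP size or Shh amplitude) against the
#' parameter multiplier, with a +/- SE ribbon, on a log multiplier axis.
#'
#' @param object An `fp_sensitivity` tibble from [sensitivity_scan()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$multiplier, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~param) +
    ggplot2::labs(x = "fold change of parameter",
                  y = unique(object$observable)) +
    ggplot2::theme_minimal()
}

#' Plot the floor-plate size distribution of a screen
#'
#' Histogram of final FP sizes over the successful visits.
#'
#' @param object An `fp_screen` tibble from [run_screen()].
#' @param binwidth Histogram bin width, um.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_screen <- function(object, binwidth = 5, ...) {
  d <- dplyr::filter(object, .data$success)
  ggplot2::ggplot(d, ggplot2::aes(.data$l_fp)) +
    ggplot2::geom_histogram(ggplot2::aes(
      y = ggplot2::after_stat(!!rlang::sym("density"))),
      binwidth = binwidth, boundary = 0,
      fill = "grey40", colour = "white") +
    ggplot2::labs(x = expression(l[FP] ~ (mu * m)), y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a growth or source sweep
#'
#' Relative FP size over time per growth condition, or final FP size per
#' source condition.
#'
#' @param object An `fp_sweep` tibble from [growth_sweep()].
#' @param y One of `"rel_fp"`, `"l_fp"`, `"a_shh"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_sweep <- function(object, y = c("rel_fp", "l_fp", "a_shh"),
                              ...) {
  y <- match.arg(y)
  ym <- paste0(y, "_mean")
  ys <- paste0(y, "_se")
  ggplot2::ggplot(object, ggplot2::aes(
    .data$time, .data[[ym]], colour = .data$condition,
    linetype = .data$shh_fp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[ym]] - .data[[ys]],
                                      ymax = .data[[ym]] + .data[[ys]],
                                      fill = .data$condition),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = y, linetype = "with Shh^FP") +
    ggplot2::theme_minimal()
}

#' Plot a gradient fit
#'
#' Shh profile (log scale) with the fitted exponential over the fit
#' window.
#'
#' @param object An `fp_gradient_fit`.
#' @param state The `fp_state` the fit was computed from.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fp_gradient_fit <- function(object, state, ...) {
  nb <- length(state$S)
  x <- (seq_len(nb) - 0.5) * state$L / nb
  d <- tibble::tibble(x = x, S = state$S)
  xfit <- seq(object$fit_window[1], object$fit_window[2], length.out = 50)
  dfit <- tibble::tibble(
    x = xfit,
    S = object$A_shh * exp(-(xfit) / object$lambda_shh))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$S)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = dfit, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "position (µm)", y = "Shh (a.u.)") +
    ggplot2::theme_minimal()
}
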