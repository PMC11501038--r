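#' Draw interaction parameters log-uniformly from the screen ranges
#'
#' Each of the seven screened parameters is drawn log-uniformly over its
#' range: 0.005--5000 for the Shh activation strengths, repressor
#' affinities and the floor-plate Shh production strength, and
#' 5e-6--5 for the two basal activation constants.
#'
#' @param n Number of draws.
#' @return A tibble with `n` rows and one column per screened parameter.
#'   Use [as_fp_params()] on a row to obtain a full parameter set.
#' @export
#' @examples
#' set.seed(1)
#' sample_params(3)
sample_params <- function(n = 1) {
  r <- .screen_ranges()
  draws <- lapply(.screen_param_names, function(nm) {
    10^stats::runif(n, log10(r$lo[[nm]]), log10(r$hi[[nm]]))
  })
  names(draws) <- .screen_param_names
  tibble::as_tibble(draws)
}

#' Propose a neighbouring parameter set for the random walk
#'
#' Multiplies each screened parameter by an independent log-normal factor
#' exp(z), z ~ N(0, sd^2), and clips the result to the screen ranges.
#'
#' @param p An `fp_params` object, a one-row tibble of screened
#'   parameters, or a named list.
#' @param sd Standard deviation of the log-normal factors (0.2 in the
#'   screen).
#' @return Same type as the input (`fp_params` in, `fp_params` out;
#'   tibble in, one-row tibble out).
#' @export
propose_params <- function(p, sd = 0.2) {
  r <- .screen_ranges()
  vals <- if (inherits(p, "fp_params")) unlist(p[.screen_param_names])
          else unlist(as.list(p)[.screen_param_names])
  fac <- exp(stats::rnorm(length(vals), 0, sd))
  new <- pmin(pmax(vals * fac, r$lo), r$hi)
  if (inherits(p, "fp_params")) {
    q <- unclass(p)
    q[.screen_param_names] <- as.list(new)
    return(structure(q, class = "fp_params"))
  }
  tibble::as_tibble(as.list(new))
}

#' Evaluate the screen success criteria on a trajectory
#'
#' Applies the five criteria that define a biologically plausible floor
#' plate, evaluated at the end of the run unless stated:
#' (i) a two-domain pattern -- F > N in the ventral-most bin, the F
#' domain contiguous from x = 0 with no dorsal F islands, and a non-empty
#' N domain; (ii) a monotonically decaying Shh profile, enforced as S at
#' the dorsal-most bin at most 2% of `S_init`; (iii) Shh and F
#' concentrations within an order of magnitude of each other, 0.1 <=
#' max(S)/max(F) <= 10; (iv) FP length between 5% and 25% of tissue
#' length; (v) FP establishment time between 2.5 h and 20 h.
#'
#' @param traj An `fp_trajectory` integrated to `t_end`.
#' @param source The [source_config()] used (supplies `S_init` for
#'   criterion ii); defaults to the trajectory's own source.
#' @return A one-row tibble: `pass_i` .. `pass_v`, `success` (their
#'   conjunction), plus the measured `l_fp`, `rel_fp`, `t_est`,
#'   `shh_f_ratio`, `a_shh`, `lambda_shh` (`NA` if the gradient fit
#'   fails) and `L_end`.
#' @export
evaluate_criteria <- function(traj, source = NULL) {
  stopifnot(inherits(traj, "fp_trajectory"))
  source <- source %||% traj$source
  st <- get_state(traj)
  nb <- length(st$F)
  above <- st$F > st$N
  n_run <- match(FALSE, above, nomatch = nb + 1L) - 1L
  l_fp <- n_run * st$L / nb
  pass_i <- above[1] && n_run < nb && !any(above[(n_run + 1):nb])
  pass_ii <- st$S[nb] <= 0.02 * source$S_init
  maxF <- max(st$F)
  ratio <- if (maxF > 0) max(st$S) / maxF else Inf
  pass_iii <- is.finite(ratio) && ratio >= 0.1 && ratio <= 10
  pass_iv <- l_fp / st$L >= 0.05 && l_fp / st$L <= 0.25
  t_est <- establishment_time(traj)
  pass_v <- !is.na(t_est) && t_est >= 2.5 && t_est <= 20
  lambda <- tryCatch(gradient_fit(st)$lambda_shh, error = function(e) NA_real_)
  tibble::tibble(
    pass_i = pass_i, pass_ii = pass_ii, pass_iii = pass_iii,
    pass_iv = pass_iv, pass_v = pass_v,
    success = pass_i && pass_ii && pass_iii && pass_iv && pass_v,
    l_fp = l_fp, rel_fp = l_fp / st$L, t_est = t_est,
    shh_f_ratio = ratio, a_shh = st$S[1], lambda_shh = lambda,
    L_end = st$L)
}

.failed_visit_row <- function() {
  tibble::tibble(
    pass_i = FALSE, pass_ii = FALSE, pass_iii = FALSE,
    pass_iv = FALSE, pass_v = FALSE, success = FALSE,
    l_fp = NA_real_, rel_fp = NA_real_, t_est = NA_real_,
    shh_f_ratio = NA_real_, a_shh = NA_real_, lambda_shh = NA_real_,
    L_end = NA_real_)
}

#' Random-walk computational screen over the interaction parameters
#'
#' Explores the seven-dimensional logarithmic parameter space. Each chain
#' draws parameter sets log-uniformly ([sample_params()]) until one
#' satisfies all success criteria; thereafter new sets are proposed from
#' the most recent successful set by log-normal perturbation
#' ([propose_params()]), so the walk stays anchored in the success
#' region. Every evaluated set -- including pre-success random draws and
#' failed proposals -- counts as one visit. Simulations that fail
#' numerically are recorded as failed visits and the walk continues.
#'
#' Screen simulations use the default pulse source, default linear
#' growth and no expression noise, matching the conditions under which
#' the success criteria were formulated.
#'
#' @param n_chains Number of independent chains.
#' @param n_visits Parameter sets visited per chain.
#' @param seed Optional RNG seed set before the screen for
#'   reproducibility.
#' @param growth,source Simulation configuration (defaults: linear
#'   growth, pulse source).
#' @param dt,record_every Passed to [simulate_tissue()].
#' @param fixed Named list of overrides for the fixed rates (e.g.
#'   `list(gamma_N = 1.44)`), applied to every visited set.
#' @param progress Print a line every `progress` visits (0 = quiet).
#' @return A tibble of class `fp_screen`, one row per visit: `chain`,
#'   `step`, the seven screened parameters, the criteria report of
#'   [evaluate_criteria()] and a `phase` column (`"search"` while the
#'   chain is still drawing uniformly, `"walk"` afterwards).
#' @export
run_screen <- function(n_chains = 1, n_visits = 1000, seed = NULL,
                       growth = growth_schedule(),
                       source = source_config(),
                       dt = NULL, record_every = 1 / 6,
                       fixed = list(), progress = 0) {
  stopifnot(n_visits >= 0, n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_chains * n_visits)
  k <- 0L
  for (chain in seq_len(n_chains)) {
    current <- NULL   # last successful screened-parameter tibble row
    for (step in seq_len(n_visits)) {
      cand <- if (is.null(current)) sample_params(1) else
        propose_params(current)
      p <- do.call(as_fp_params, c(list(cand), fixed))
      rep <- tryCatch(
        evaluate_criteria(
          simulate_tissue(p, growth, source, dt = dt,
                          record_every = record_every),
          source),
        error = function(e) .failed_visit_row())
      if (isTRUE(rep$success)) current <- cand
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(chain = chain, step = step,
                       phase = if (is.null(current) ||
                                   (isTRUE(rep$success) && step == 1))
                         "search" else "walk"),
        cand, rep)
      if (progress > 0 && step %% progress == 0)
        message(sprintf("chain %d: %d/%d visits, %d successes so far",
                        chain, step, n_visits,
                        sum(vapply(rows[seq_len(k)],
                                   function(r) r$success, logical(1)))))
    }
  }
  if (k == 0L) {
    out <- dplyr::bind_cols(
      tibble::tibble(chain = integer(), step = integer(),
                     phase = character()),
      sample_params(0), .failed_visit_row()[0, ])
    class(out) <- c("fp_screen", class(out))
    return(out)
  }
  out <- dplyr::bind_rows(rows[seq_len(k)])
  # phase bookkeeping: a step is "search" iff no success seen before it
  out <- out |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(phase = ifelse(cumsum(dplyr::lag(.data$success,
                                                   default = FALSE)) == 0,
                                 "search", "walk")) |>
    dplyr::ungroup()
  class(out) <- c("fp_screen", class(out))
  attr(out, "growth") <- growth
  attr(out, "source") <- source
  attr(out, "fixed") <- fixed
  out
}

#' Sensitivity of a successful network to floor-plate-derived Shh
#'
#' Re-simulates a parameter set with `kappa_F_to_S = 0` (no Shh
#' production in the floor plate, all else identical) and classifies the
#' response of the FP size: `"sensitive"` if the FP is lost entirely,
#' `"insensitive"` if the change is at most one spatial bin,
#' `"increased"` if the FP grows by more than one bin, `"partial"`
#' otherwise.
#'
#' @param p Parameter set of a network successful under default
#'   conditions (`fp_params`, one-row tibble or named list).
#' @param base_l_fp FP size (um) of the unperturbed run.
#' @inheritParams run_screen
#' @return A one-row tibble: `l_fp_perturbed`, `delta_l_fp` (base minus
#'   perturbed) and `sens_class`.
#' @export
classify_sensitivity <- function(p, base_l_fp,
                                 growth = growth_schedule(),
                                 source = source_config(),
                                 dt = NULL, record_every = 1 / 6) {
  p0 <- as_fp_params(p, kappa_F_to_S = 0)
  traj <- simulate_tissue(p0, growth, source, dt = dt,
                          record_every = record_every)
  l_pert <- fp_size(get_state(traj))
  delta <- base_l_fp - l_pert
  bin <- tissue_length(growth, growth$t_end) / traj$n_bins
  cls <- if (l_pert == 0 && base_l_fp > 0) "sensitive"
         else if (abs(delta) <= bin + 1e-9) "insensitive"
         else if (delta < -bin) "increased"
         else "partial"
  tibble::tibble(l_fp_perturbed = l_pert, delta_l_fp = delta,
                 sens_class = cls)
}

#' Classify all successful networks of a screen
#'
#' Runs [classify_sensitivity()] for every successful visit of a screen
#' and appends `l_fp_perturbed`, `delta_l_fp` and `sens_class` columns
#' (`NA` for unsuccessful visits).
#'
#' @param screen An `fp_screen` tibble from [run_screen()].
#' @inheritParams run_screen
#' @param progress Print a message every `progress` classified networks
#'   (0 = quiet).
#' @return The screen tibble with classification columns added.
#' @export
classify_screen <- function(screen, growth = NULL, source = NULL,
                            dt = NULL, record_every = 1 / 6,
                            progress = 0) {
  growth <- growth %||% attr(screen, "growth") %||% growth_schedule()
  source <- source %||% attr(screen, "source") %||% source_config()
  fixed <- attr(screen, "fixed") %||% list()
  idx <- which(screen$success)
  res <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    p <- do.call(as_fp_params,
                 c(list(screen[i, .screen_param_names]), fixed))
    res[[j]] <- classify_sensitivity(p, screen$l_fp[i], growth, source,
                                     dt, record_every)
    if (progress > 0 && j %% progress == 0)
      message(sprintf("classified %d/%d successful networks",
                      j, length(idx)))
  }
  out <- screen
  out$l_fp_perturbed <- NA_real_
  out$delta_l_fp <- NA_real_
  out$sens_class <- NA_character_
  if (length(idx)) {
    block <- dplyr::bind_rows(res)
    out$l_fp_perturbed[idx] <- block$l_fp_perturbed
    out$delta_l_fp[idx] <- block$delta_l_fp
    out$sens_class[idx] <- block$sens_class
  }
  out
}
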