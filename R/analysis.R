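#' Select successful networks with a target relative floor-plate size
#'
#' Uniformly samples `n` successful screen records whose relative FP size
#' at the end of the run lies within `tol` of `target_rel_fp`, optionally
#' restricted to one sensitivity class. Mirrors the "n networks with
#' relative FP size of 20%" subsets used by the sensitivity and sweep
#' analyses.
#'
#' @param records A screen tibble ([run_screen()], optionally classified
#'   by [classify_screen()]).
#' @param target_rel_fp Target relative FP size (fraction of tissue
#'   length).
#' @param tol Tolerance on the relative FP size.
#' @param n Number of networks to sample.
#' @param sens_class Optional class filter (e.g. `"insensitive"`).
#' @return A tibble of `n` sampled rows (all columns of `records`).
#' @export
select_subset <- function(records, target_rel_fp = 0.2, tol = 0.01,
                          n = 10, sens_class = NULL) {
  pool <- dplyr::filter(records, .data$success,
                        abs(.data$rel_fp - target_rel_fp) <= tol)
  if (!is.null(sens_class))
    pool <- dplyr::filter(pool, .data$sens_class %in% !!sens_class)
  if (nrow(pool) < n)
    stop(sprintf(
      "only %d qualifying networks available (requested %d) for target %.3g +/- %.3g",
      nrow(pool), n, target_rel_fp, tol), call. = FALSE)
  pool[sample.int(nrow(pool), n), ]
}

.networks_list <- function(networks, fixed = list()) {
  if (inherits(networks, "fp_params")) return(list(networks))
  if (is.data.frame(networks)) {
    return(lapply(seq_len(nrow(networks)), function(i)
      do.call(as_fp_params,
              c(list(networks[i, intersect(names(networks),
                                           names(formals(fp_params)))]),
                fixed))))
  }
  lapply(networks, as_fp_params)
}

#' One-parameter sensitivity scan
#'
#' Re-simulates each network with a single parameter scaled by a grid of
#' multipliers (log-equispaced from `from` to `to`), all other
#' parameters held at their network-specific values, and records the
#' chosen observable at the end of the run: the relative FP size or the
#' Shh amplitude.
#'
#' @param networks Networks to scan: a tibble of screen rows, a list of
#'   `fp_params`, or a single `fp_params`.
#' @param param_name One of the [fp_params()] field names.
#' @param observable `"rel_fp"` or `"amplitude"`.
#' @param n_steps Number of multipliers (40 in the reference analyses).
#' @param from,to Multiplier range endpoints.
#' @inheritParams run_screen
#' @return A tibble of class `fp_sensitivity`: `param`, `multiplier`,
#'   `mean`, `se`, `n_ok`, `n_fail`, `observable`.
#' @export
sensitivity_scan <- function(networks, param_name,
                             observable = c("rel_fp", "amplitude"),
                             n_steps = 40, from = 0.1, to = 10,
                             growth = growth_schedule(),
                             source = source_config(),
                             dt = NULL, record_every = 1 / 6) {
  observable <- match.arg(observable)
  stopifnot(param_name %in% names(formals(fp_params)))
  nets <- .networks_list(networks)
  mult <- 10^seq(log10(from), log10(to), length.out = n_steps)
  rows <- purrr::map(mult, function(m) {
    vals <- purrr::map_dbl(nets, function(p) {
      q <- unclass(p)
      q[[param_name]] <- q[[param_name]] * m
      tryCatch({
        traj <- simulate_tissue(structure(q, class = "fp_params"),
                                growth, source, dt = dt,
                                record_every = record_every)
        st <- get_state(traj)
        if (observable == "rel_fp") fp_size(st) / st$L else st$S[1]
      }, error = function(e) NA_real_)
    })
    ok <- !is.na(vals)
    tibble::tibble(param = param_name, multiplier = m,
                   mean = mean(vals[ok]),
                   se = stats::sd(vals[ok]) / sqrt(sum(ok)),
                   n_ok = sum(ok), n_fail = sum(!ok),
                   observable = observable)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fp_sensitivity", class(out))
  out
}

#' Growth-rate sweep
#'
#' Simulates each network under a set of linear growth rates (and
#' optionally exponential growth), with or without floor-plate-derived
#' Shh, and returns the time course of absolute and relative FP size and
#' Shh amplitude, averaged over networks.
#'
#' @inheritParams sensitivity_scan
#' @param kp Linear growth rates to test, um/h.
#' @param include_exponential Also run the exponential schedule
#'   (L = L0 exp(t/tau)).
#' @param kappa_off Re-run with `kappa_F_to_S = 0` (no Shh^FP).
#' @param L0,t_end,tau Growth schedule settings shared by all
#'   conditions.
#' @return A tibble of class `fp_sweep`: `condition`, `kp`, `shh_fp`,
#'   `time`, `L`, mean and standard error of `l_fp`, `rel_fp`, `a_shh`,
#'   and `n` networks.
#' @export
growth_sweep <- function(networks, kp = c(0, 5, 10),
                         include_exponential = TRUE, kappa_off = FALSE,
                         source = source_config(),
                         L0 = 100, t_end = 60, tau = 43.3,
                         dt = NULL, record_every = 1 / 6) {
  nets <- .networks_list(networks)
  conds <- c(
    purrr::map(kp, function(k)
      list(label = sprintf("kp=%g", k),
           g = growth_schedule("linear", L0 = L0, k_p = k, t_end = t_end))),
    if (include_exponential)
      list(list(label = "exponential",
                g = growth_schedule("exponential", L0 = L0, tau = tau,
                                    t_end = t_end))))
  variants <- if (kappa_off) c(TRUE, FALSE) else TRUE
  rows <- purrr::map(conds, function(cond) {
    purrr::map(variants, function(with_fp_shh) {
      mets <- purrr::map(nets, function(p) {
        if (!with_fp_shh) p <- as_fp_params(p, kappa_F_to_S = 0)
        trajectory_metrics(
          simulate_tissue(p, cond$g, source, dt = dt,
                          record_every = record_every))
      })
      agg <- dplyr::bind_rows(mets, .id = "net") |>
        dplyr::group_by(.data$time, .data$L) |>
        dplyr::summarise(
          l_fp_mean = mean(.data$l_fp), l_fp_se = .se(.data$l_fp),
          rel_fp_mean = mean(.data$rel_fp), rel_fp_se = .se(.data$rel_fp),
          a_shh_mean = mean(.data$a_shh), a_shh_se = .se(.data$a_shh),
          n = dplyr::n(), .groups = "drop")
      agg$condition <- cond$label
      agg$kp <- if (grepl("^kp=", cond$label))
        as.numeric(sub("kp=", "", cond$label)) else NA_real_
      agg$shh_fp <- with_fp_shh
      agg
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("fp_sweep", class(out))
  out
}

.se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0

#' Shh source sweep
#'
#' Simulates each network under varied source conditions -- initial pulse
#' magnitudes, constant boundary fluxes, and fluxes removed at given
#' times -- and reports the final FP size (absolute and relative) and
#' Shh amplitude per condition.
#'
#' @inheritParams sensitivity_scan
#' @param S_init Pulse magnitudes to test (a.u.); `numeric(0)` to skip.
#' @param j_shh Constant flux magnitudes (a.u./s); `numeric(0)` to skip.
#' @param t_off Flux removal times (h); each is combined with every
#'   value of `j_shh`.
#' @param kappa_off Additionally run every condition with
#'   `kappa_F_to_S = 0`.
#' @return A tibble of class `fp_sweep_src`: `condition`, `S_init`,
#'   `j_shh`, `t_off`, `shh_fp`, per-network final `l_fp`, `rel_fp`,
#'   `a_shh` plus network index.
#' @export
source_sweep <- function(networks, S_init = numeric(0),
                         j_shh = numeric(0), t_off = numeric(0),
                         kappa_off = FALSE,
                         growth = growth_schedule(),
                         dt = NULL, record_every = 1 / 6) {
  nets <- .networks_list(networks)
  conds <- c(
    purrr::map(S_init, function(s)
      list(label = sprintf("pulse S_init=%g", s),
           src = source_config("pulse", S_init = s),
           S_init = s, j = NA_real_, toff = NA_real_)),
    purrr::map(j_shh, function(j)
      list(label = sprintf("flux j=%g", j),
           src = source_config("flux", j_shh = j),
           S_init = NA_real_, j = j, toff = NA_real_)),
    purrr::flatten(purrr::map(j_shh, function(j)
      purrr::map(t_off, function(to)
        list(label = sprintf("flux j=%g off at %g h", j, to),
             src = source_config("flux_off", j_shh = j, t_off = to),
             S_init = NA_real_, j = j, toff = to)))))
  variants <- if (kappa_off) c(TRUE, FALSE) else TRUE
  rows <- purrr::map(conds, function(cond) {
    purrr::map(variants, function(with_fp_shh) {
      purrr::imap(nets, function(p, i) {
        if (!with_fp_shh) p <- as_fp_params(p, kappa_F_to_S = 0)
        st <- get_state(simulate_tissue(p, growth, cond$src, dt = dt,
                                        record_every = record_every))
        tibble::tibble(condition = cond$label, S_init = cond$S_init,
                       j_shh = cond$j, t_off = cond$toff,
                       shh_fp = with_fp_shh, net = i,
                       l_fp = fp_size(st), rel_fp = fp_size(st) / st$L,
                       a_shh = st$S[1])
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  class(out) <- c("fp_sweep_src", class(out))
  out
}

#' Floor-plate formation time versus N degradation rate
#'
#' Re-simulates each network with the degradation rate of N scaled by
#' each multiplier and reports the mean formation time T_FP (the time at
#' which the relative FP size reaches its final value) with its standard
#' error.
#'
#' @inheritParams sensitivity_scan
#' @param gamma_multipliers Multipliers applied to `gamma_N`.
#' @param tol Tolerance passed to [formation_time()].
#' @return A tibble: `gamma_multiplier`, `mean_t_fp`, `sem`, `n` (plus
#'   the per-network times in the list-column `t_fp`).
#' @export
tfp_vs_degradation <- function(networks, gamma_multipliers = c(1, 2),
                               tol = 0.01,
                               growth = growth_schedule(),
                               source = source_config(),
                               dt = NULL, record_every = 1 / 6) {
  nets <- .networks_list(networks)
  rows <- purrr::map(gamma_multipliers, function(m) {
    tfp <- purrr::map_dbl(nets, function(p) {
      p2 <- as_fp_params(p, gamma_N = p$gamma_N * m)
      formation_time(
        simulate_tissue(p2, growth, source, dt = dt,
                        record_every = record_every), tol = tol)
    })
    ok <- !is.na(tfp)
    tibble::tibble(gamma_multiplier = m, mean_t_fp = mean(tfp[ok]),
                   sem = .se(tfp[ok]), n = sum(ok),
                   t_fp = list(tfp))
  })
  dplyr::bind_rows(rows)
}

#' Relation between Shh amplitude and floor-plate size
#'
#' Bins records by FP size, reports the mean amplitude (+/- SE) per bin,
#' and fits a continuous two-segment summary (linear through a
#' breakpoint, then flat) by profiling the breakpoint over the observed
#' size range. The Shh amplitude is expected to grow linearly with FP
#' size while the FP is small compared to the gradient decay length and
#' to saturate for large FPs.
#'
#' @param records A tibble with columns `l_fp` and `a_shh` (e.g.
#'   successful screen rows).
#' @param bin_width FP-size bin width, um.
#' @return A tibble of class `fp_ampfp` of per-bin summaries (`l_fp_mid`,
#'   `mean_a`, `se`, `n`), with attributes `slope`, `breakpoint` and
#'   `plateau_detected` describing the two-segment fit.
#' @export
amplitude_fp_relation <- function(records, bin_width = 10) {
  d <- dplyr::filter(records, is.finite(.data$l_fp), is.finite(.data$a_shh))
  stopifnot(nrow(d) >= 3)
  breaks <- seq(0, max(d$l_fp) + bin_width, by = bin_width)
  bins <- d |>
    dplyr::mutate(bin = cut(.data$l_fp, breaks, right = FALSE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(l_fp_mid = mean(.data$l_fp),
                     mean_a = mean(.data$a_shh),
                     se = .se(.data$a_shh), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$bin))
  # two-segment fit: A = s * min(l, b); profile b over the data range
  sse_at <- function(b) {
    z <- pmin(d$l_fp, b)
    s <- sum(z * d$a_shh) / sum(z^2)
    c(sse = sum((d$a_shh - s * z)^2), slope = s)
  }
  cand <- sort(unique(c(d$l_fp, max(d$l_fp))))
  cand <- cand[cand > 0]
  fits <- vapply(cand, sse_at, numeric(2))
  best <- which.min(fits["sse", ])
  bhat <- cand[best]
  plateau <- bhat < max(d$l_fp) - 1e-9
  structure(bins, class = c("fp_ampfp", class(bins)),
            slope = unname(fits["slope", best]),
            breakpoint = if (plateau) bhat else NA_real_,
            plateau_detected = plateau)
}
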