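#' Generate synthetic fluorescence-intensity profiles
#'
#' Emulates quantified ventral-to-dorsal Shh immunostaining profiles as
#' exponential decays with additive flat background and Gaussian noise:
#' I(x) = amplitude * exp(-x / decay_length) + background + noise. The
#' defaults mimic an E10.5-like section: a 400 um DV axis sampled every
#' micron with a decay length of 23.45 um.
#'
#' @param n_profiles Number of profiles.
#' @param amplitude Peak intensity, a.u.
#' @param decay_length Exponential decay length, um.
#' @param dv_length DV axis length, um.
#' @param background Flat background intensity, a.u.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param sampling_step Position sampling interval, um.
#' @param group Group label attached to every profile.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `profile_id`, `group`, `position_um`,
#'   `intensity`.
#' @export
generate_profiles <- function(n_profiles = 10, amplitude = 100,
                              decay_length = 23.45, dv_length = 400,
                              background = 10, noise_sd = 2,
                              sampling_step = 1, group = "control",
                              seed = NULL) {
  stopifnot(amplitude > 0, decay_length > 0, dv_length > 0,
            sampling_step > 0, background >= 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, dv_length, by = sampling_step)
  purrr::map(seq_len(n_profiles), function(i) {
    tibble::tibble(
      profile_id = sprintf("%s_%02d", group, i), group = group,
      position_um = x,
      intensity = amplitude * exp(-x / decay_length) + background +
        stats::rnorm(length(x), 0, noise_sd))
  }) |> dplyr::bind_rows()
}

#' Curated reference networks by sensitivity class
#'
#' Returns parameter sets of screened, successful networks of the
#' requested Shh^FP-sensitivity class from the classified network cache
#' shipped with the package (built by [build_network_cache()] from a
#' pinned-seed scaled-down screen), so that analyses and tests have
#' deterministic inputs without re-running the screen.
#'
#' @param sens_class `"insensitive"`, `"sensitive"`, `"partial"` or
#'   `"increased"`.
#' @param n Number of networks required (`Inf` for all available).
#' @param cache Path to a cache JSON; defaults to the shipped cache.
#' @return A tibble with the screened parameters plus `l_fp`, `rel_fp`,
#'   `a_shh`, `t_est`, `delta_l_fp` and `sens_class` columns.
#' @export
reference_networks <- function(sens_class = c("insensitive", "sensitive",
                                              "partial", "increased"),
                               n = Inf, cache = NULL) {
  sens_class <- match.arg(sens_class)
  tbl <- load_network_cache(cache)
  hit <- dplyr::filter(tbl, .data$sens_class == !!sens_class)
  if (is.finite(n) && nrow(hit) < n) {
    counts <- table(tbl$sens_class)
    stop(sprintf(
      "requested %d '%s' networks but the cache holds %d (cache counts: %s)",
      n, sens_class, nrow(hit),
      paste(names(counts), counts, sep = "=", collapse = ", ")),
      call. = FALSE)
  }
  if (is.finite(n)) hit <- hit[seq_len(n), ]
  hit
}

#' @rdname reference_networks
#' @export
load_network_cache <- function(cache = NULL) {
  cache <- cache %||% system.file("extdata", "network_cache.json",
                                  package = "shhfp", mustWork = TRUE)
  tibble::as_tibble(jsonlite::fromJSON(cache)$networks)
}

#' Build a classified network cache
#'
#' Runs a scaled-down screen with a pinned seed, classifies every
#' successful network by its sensitivity to floor-plate-derived Shh, and
#' writes up to `max_networks` classified networks to a JSON cache for
#' use by [reference_networks()].
#'
#' @param path Output JSON path.
#' @param n_chains,n_visits Screen size (chains x visits per chain).
#' @param seed Screen seed.
#' @param max_networks Cap on stored networks. The kept set is
#'   stratified: all networks of the rarer sensitivity classes, a block
#'   of insensitive networks with relative FP size near 20% (the subset
#'   the sweep analyses use), and a spread of the remaining successes.
#' @param progress Passed to [run_screen()] / [classify_screen()].
#' @param classified Optional pre-classified screen tibble; skips the
#'   screen/classification recomputation.
#' @return The cache tibble, invisibly.
#' @export
build_network_cache <- function(path, n_chains = 4, n_visits = 2500,
                                seed = 42, max_networks = 150,
                                progress = 0, classified = NULL) {
  cls <- classified %||% classify_screen(
    run_screen(n_chains = n_chains, n_visits = n_visits, seed = seed,
               progress = progress),
    progress = progress)
  succ <- dplyr::filter(cls, .data$success)
  rare <- dplyr::filter(succ, .data$sens_class != "insensitive")
  ins <- dplyr::filter(succ, .data$sens_class == "insensitive")
  ins20 <- dplyr::filter(ins, abs(.data$rel_fp - 0.2) <= 0.025)
  n_rare <- min(nrow(rare), 60)
  n_20 <- min(nrow(ins20), 30)
  pick_spread <- function(d, k) {
    if (nrow(d) <= k) return(d)
    d[unique(round(seq(1, nrow(d), length.out = k))), ]
  }
  keep <- dplyr::bind_rows(
    pick_spread(rare, n_rare),
    ins20[seq_len(n_20), ],
    pick_spread(dplyr::anti_join(ins, ins20[seq_len(n_20), ],
                                 by = c("chain", "step")),
                max(0, max_networks - n_rare - n_20)))
  keep <- dplyr::distinct(keep, .data$chain, .data$step, .keep_all = TRUE)
  cols <- c(.screen_param_names, "l_fp", "rel_fp", "a_shh", "t_est",
            "lambda_shh", "delta_l_fp", "sens_class", "L_end",
            "chain", "step")
  keep <- keep[, cols]
  obj <- list(
    meta = list(n_chains = n_chains, n_visits = n_visits, seed = seed,
                n_success = nrow(succ),
                generator = "shhfp::build_network_cache"),
    networks = keep)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(keep)
}

#' Hand-constructed trajectories for testing metrics and criteria
#'
#' Builds small deterministic `fp_trajectory` objects with known metric
#' values: `"no_fp"` (F never exceeds N), `"fp_30pct"` (FP occupying 30%
#' of the tissue, too large for the screen criteria), `"fp_20pct"` (a
#' compliant FP with an exponential Shh gradient), `"dorsal_island"`
#' (a ventral FP plus a detached dorsal F > N island) and `"ramp12h"`
#' (relative FP size ramping until 12 h, flat afterwards).
#'
#' @param kind Fixture name.
#' @param n_bins Spatial bins.
#' @return An `fp_trajectory`.
#' @export
make_criteria_fixture <- function(kind = c("no_fp", "fp_30pct",
                                           "fp_20pct", "dorsal_island",
                                           "ramp12h"),
                                  n_bins = 100) {
  kind <- match.arg(kind)
  growth <- growth_schedule()
  source <- source_config()
  times <- seq(0, growth$t_end, by = 1)
  L <- tissue_length(growth, times)
  nt <- length(times)
  Fm <- matrix(0, n_bins, nt)
  Nm <- matrix(10, n_bins, nt)
  Sm <- matrix(0, n_bins, nt)
  x_end <- (seq_len(n_bins) - 0.5) / n_bins
  fp_frac <- function(kind, t) {
    switch(kind,
           no_fp = 0,
           fp_30pct = 0.30,
           fp_20pct = 0.20,
           dorsal_island = 0.05,
           ramp12h = 0.20 * pmin(t, 12) / 12)
  }
  for (k in seq_len(nt)) {
    t <- times[k]
    frac <- fp_frac(kind, t)
    nfp <- floor(frac * n_bins + 1e-9)
    if (t >= 5 && nfp > 0) {         # establish at 5 h
      Fm[seq_len(nfp), k] <- 100
      Nm[seq_len(nfp), k] <- 1
    }
    if (kind == "dorsal_island" && t >= 5) {
      isl <- 51:56
      Fm[isl, k] <- 100
      Nm[isl, k] <- 1
    }
    # exponential Shh gradient, amplitude growing to 300 a.u.
    A <- 300 * pmin(t, 10) / 10
    Sm[, k] <- A * exp(-x_end * L[k] / 23.45)
  }
  t_est <- if (fp_frac(kind, growth$t_end) > 0) 5 else NA_real_
  structure(list(time = times, L = L, F = Fm, N = Nm, S = Sm,
                 t_est = t_est, dt = NA_real_, n_bins = n_bins,
                 params = NULL, growth = growth, source = source,
                 noise = NULL),
            class = "fp_trajectory")
}
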