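#' Background-subtract and smooth a fluorescence-intensity profile
#'
#' Processes a ventral-to-dorsal fluorescence-intensity (FI) profile the
#' way immunostaining quantifications are processed: the background,
#' defined as the minimum FI within 10--90% of the dorsoventral (DV)
#' length, is subtracted (negative values clamped at zero) and the
#' profile is then smoothed with a centred moving-average filter of 5 um
#' width, shrinking the window at the profile edges.
#'
#' @param profile A data frame with columns `position_um` (strictly
#'   increasing, uniformly spaced) and `intensity`; other columns are
#'   preserved.
#' @param window Moving-average window, um.
#' @return A tibble like `profile` with processed `intensity`.
#' @export
process_profile <- function(profile, window = 5) {
  stopifnot(all(c("position_um", "intensity") %in% names(profile)))
  x <- profile$position_um
  y <- profile$intensity
  stopifnot(length(x) >= 2, all(diff(x) > 0), all(is.finite(y)))
  step <- diff(x)
  if (max(step) - min(step) > 1e-6 * max(step))
    stop("positions must be uniformly spaced", call. = FALSE)
  step <- step[1]
  if (step > window)
    stop("sampling interval exceeds the smoothing window", call. = FALSE)
  dv <- max(x) - min(x)
  if (dv <= 0) stop("degenerate profile", call. = FALSE)
  in_win <- x >= min(x) + 0.1 * dv & x <= min(x) + 0.9 * dv
  bg <- min(y[in_win])
  y <- pmax(y - bg, 0)
  hw <- floor(window / step / 2)
  if (2 * hw + 1 > length(y))
    stop("profile shorter than the smoothing window", call. = FALSE)
  sm <- vapply(seq_along(y), function(i) {
    lo <- max(1L, i - hw)
    hi <- min(length(y), i + hw)
    mean(y[lo:hi])
  }, numeric(1))
  out <- tibble::as_tibble(profile)
  out$intensity <- sm
  out
}

#' Group mean fluorescence profile with confidence band
#'
#' Computes the per-position mean FI profile of a group with a
#' pointwise 95% confidence interval, subtracts the background of the
#' mean profile itself (minimum within 10--90% of DV length), shifts the
#' origin so that x = 0 lies at the control mean-profile peak (the
#' global maximum within the ventral 30% of DV length), and normalizes
#' all intensities to the control group's mean maximum.
#'
#' @param profiles A data frame of processed profiles with columns
#'   `position_um`, `intensity` and `profile_id` (one profile per id).
#' @param control Same layout; the control group used for origin and
#'   normalization. May be the same object as `profiles`.
#' @param peak_fraction Ventral fraction of the DV axis within which the
#'   peak is sought.
#' @return A tibble with columns `position_um` (origin at the control
#'   peak), `mean_fi`, `ci_lo`, `ci_hi` and `n` (profiles per
#'   position). Intensities are normalized so the control group's mean
#'   maximum equals 1.
#' @export
mean_profile <- function(profiles, control = profiles,
                         peak_fraction = 0.3) {
  grp <- .group_mean(profiles)
  ctl <- if (identical(profiles, control)) grp else .group_mean(control)
  # background subtraction on the mean profiles
  grp <- .subtract_bg(grp)
  ctl <- .subtract_bg(ctl)
  dv <- max(ctl$position_um) - min(ctl$position_um)
  ventral <- ctl$position_um <= min(ctl$position_um) + peak_fraction * dv
  peak_pos <- ctl$position_um[ventral][which.max(ctl$mean_fi[ventral])]
  norm <- max(ctl$mean_fi)
  if (norm <= 0) stop("control mean profile has no signal", call. = FALSE)
  grp$position_um <- grp$position_um - peak_pos
  grp$mean_fi <- grp$mean_fi / norm
  grp$ci_lo <- grp$ci_lo / norm
  grp$ci_hi <- grp$ci_hi / norm
  grp
}

.group_mean <- function(profiles) {
  stopifnot(all(c("position_um", "intensity", "profile_id") %in%
                  names(profiles)))
  ids <- unique(profiles$profile_id)
  if (length(ids) < 2)
    stop("need at least 2 profiles per group", call. = FALSE)
  ref <- sort(unique(profiles$position_um[
    profiles$profile_id == ids[1]]))
  mats <- vapply(ids, function(id) {
    d <- profiles[profiles$profile_id == id, ]
    if (length(d$position_um) != length(ref) ||
        any(abs(sort(d$position_um) - ref) > 1e-6)) {
      warning("position grids differ between profiles; resampling to ",
              "the first profile's grid", call. = FALSE)
      stats::approx(d$position_um, d$intensity, xout = ref, rule = 2)$y
    } else {
      d$intensity[order(d$position_um)]
    }
  }, numeric(length(ref)))
  m <- rowMeans(mats)
  sdv <- apply(mats, 1, stats::sd)
  half <- stats::qt(0.975, df = length(ids) - 1) * sdv / sqrt(length(ids))
  tibble::tibble(position_um = ref, mean_fi = m,
                 ci_lo = m - half, ci_hi = m + half,
                 n = length(ids))
}

.subtract_bg <- function(g) {
  dv <- max(g$position_um) - min(g$position_um)
  in_win <- g$position_um >= min(g$position_um) + 0.1 * dv &
    g$position_um <= min(g$position_um) + 0.9 * dv
  bg <- min(g$mean_fi[in_win])
  g$mean_fi <- pmax(g$mean_fi - bg, 0)
  g$ci_lo <- g$ci_lo - bg
  g$ci_hi <- g$ci_hi - bg
  g
}

#' Floor-plate length from a measured area
#'
#' The neuroepithelium is a monolayer, so the FP length follows from the
#' immunostained FP area divided by the mean apicobasal thickness at the
#' ventral midline (17 um in brachial E10.5 sections).
#'
#' @param area Measured FP area, um^2.
#' @param thickness Apicobasal thickness, um.
#' @return FP length, um.
#' @export
#' @examples
#' fp_length_from_area(170)  # 10 um
fp_length_from_area <- function(area, thickness = 17) {
  if (any(thickness <= 0))
    stop("`thickness` must be strictly positive", call. = FALSE)
  if (any(area < 0)) stop("`area` must be non-negative", call. = FALSE)
  area / thickness
}
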