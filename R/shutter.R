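#' Per-trial phase and amplitude at the measurement time
#'
#' Reads LO and RO alpha phase and peak-to-peak amplitude at
#' `onset + t_measure_ms` (snapped to the nearest sample) for every
#' flash event, rejects trials whose LO/RO phases differ by more than
#' 90 degrees (circular absolute difference; exactly 90 is retained),
#' and combines retained trials by the two-point circular mean of the
#' phases and the arithmetic mean of the amplitudes.
#'
#' @param lo_series,ro_series `analytic_series` from
#'   [wavelet_transform()] of the pooled LO and RO signals.
#' @param events Event table; only `flash` rows are used and must carry
#'   an `observed` flag.
#' @param t_measure_ms Measurement time relative to stimulus onset, ms
#'   (the individual's t2, or e.g. -100 for a prestimulus control).
#' @return Data frame of class `trial_phase_amp`: `trial, lo_phase,
#'   ro_phase, lo_amp, ro_amp, combined_phase, combined_amp, observed,
#'   rejected_asynchrony` (combined fields are NA on rejected trials).
#'   The measurement time is stored in attribute `t_measure_ms`.
#' @export
trial_measures <- function(lo_series, ro_series, events, t_measure_ms) {
  stopifnot(inherits(lo_series, "analytic_series"),
            inherits(ro_series, "analytic_series"))
  events <- event_table(events)
  flashes <- events[events$type == "flash", ]
  if (!nrow(flashes)) stop("no flash events")
  if (any(is.na(flashes$observed)))
    stop("flash events must carry an 'observed' flag")
  fs <- lo_series$sampling_rate
  n <- length(lo_series$values)
  if (length(ro_series$values) != n || ro_series$sampling_rate != fs)
    stop("LO and RO series are not aligned")
  t_samp <- as.integer(round(t_measure_ms / 1000 * fs))
  idx <- time_to_sample(flashes$onset, fs) + t_samp
  if (any(idx < 1 | idx > n))
    stop("event measurement time beyond the series")
  if (any(lo_series$edge[idx] | ro_series$edge[idx]))
    stop("measurement time falls in the convolution edge region")

  lo_phase <- phase_deg(lo_series$values[idx])
  ro_phase <- phase_deg(ro_series$values[idx])
  lo_amp <- p2p_amplitude(lo_series$values[idx])
  ro_amp <- p2p_amplitude(ro_series$values[idx])
  rejected <- abs(circ_diff(lo_phase, ro_phase)) > 90
  comb_phase <- rep(NA_real_, length(idx))
  for (i in which(!rejected))
    comb_phase[i] <- circ_mean(c(lo_phase[i], ro_phase[i]))$angle
  comb_amp <- ifelse(rejected, NA_real_, (lo_amp + ro_amp) / 2)

  out <- data.frame(trial = seq_len(nrow(flashes)),
                    lo_phase = lo_phase, ro_phase = ro_phase,
                    lo_amp = lo_amp, ro_amp = ro_amp,
                    combined_phase = comb_phase, combined_amp = comb_amp,
                    observed = as.logical(flashes$observed),
                    rejected_asynchrony = rejected)
  attr(out, "t_measure_ms") <- t_measure_ms
  class(out) <- c("trial_phase_amp", "data.frame")
  out
}

#' Median split of retained trials into amplitude levels
#'
#' Per-participant median of the combined amplitude over retained trials
#' only (asynchrony rejection precedes binning); trials at or below the
#' median are `low`, above it `high`.  The median guarantees near-equal
#' level sizes regardless of the amplitude distribution's shape.
#'
#' @param trials A `trial_phase_amp` data frame.
#' @return Factor (`low`/`high`) aligned with the rows of `trials`; NA
#'   for rejected trials.  If all amplitudes are equal every trial is
#'   `low` and a warning is raised.
#' @export
amplitude_split <- function(trials) {
  keep <- !trials$rejected_asynchrony
  if (sum(keep) < 2) stop("need at least 2 retained trials to split")
  med <- stats::median(trials$combined_amp[keep])
  lab <- rep(NA_character_, nrow(trials))
  lab[keep] <- ifelse(trials$combined_amp[keep] <= med, "low", "high")
  if (all(lab[keep] == "low"))
    warning("degenerate amplitude split: all amplitudes equal")
  factor(lab, levels = c("low", "high"))
}

# Map phases to the 90-degree bin centers 0/90/180/270 with circularly
# half-open membership [c - 45, c + 45).
phase_bin_center <- function(phase_deg) {
  90 * (floor(((phase_deg + 45) %% 360) / 90) %% 4)
}

#' 2 x 4 amplitude-by-phase bin grid of observation rates
#'
#' Retained trials are split by amplitude level and by phase into
#' 90-degree bins centered on 0, 90, 180 and 270 degrees (membership
#' `[c - 45, c + 45)`, circular).  Each cell's OR is the percentage of
#' its trials observed; `delta_or` subtracts the overall OR across all
#' retained trials (a difference in percentage points, not a percent
#' change).  Empty cells get NA and are flagged.
#'
#' @param trials A `trial_phase_amp` data frame.
#' @param labels Amplitude labels from [amplitude_split()].
#' @return Data frame of class `bin_grid`, 8 rows: `amplitude,
#'   phase_center, n_trials, n_observed, or_pct, delta_or, empty`; the
#'   overall OR (percent) is in attribute `overall_or`.
#' @export
bin_grid <- function(trials, labels) {
  keep <- !trials$rejected_asynchrony
  overall <- 100 * mean(trials$observed[keep])
  centers <- c(0, 90, 180, 270)
  bin <- phase_bin_center(trials$combined_phase)
  grid <- expand.grid(amplitude = c("low", "high"), phase_center = centers)
  grid$n_trials <- 0L; grid$n_observed <- 0L
  for (r in seq_len(nrow(grid))) {
    sel <- keep & labels == grid$amplitude[r] & bin == grid$phase_center[r]
    sel[is.na(sel)] <- FALSE
    grid$n_trials[r] <- sum(sel)
    grid$n_observed[r] <- sum(trials$observed[sel])
  }
  grid$or_pct <- ifelse(grid$n_trials > 0,
                        100 * grid$n_observed / grid$n_trials, NA_real_)
  grid$delta_or <- grid$or_pct - overall
  grid$empty <- grid$n_trials == 0L
  attr(grid, "overall_or") <- overall
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Rotating-bin phase profile of delta-OR
#'
#' For each amplitude level and each integer bin center c in 0..359
#' degrees, the delta-OR (cell OR minus the overall OR over all retained
#' trials) of the 90-degree bin `[c - 45, c + 45)` within that level.
#' Bins that are empty at some centers are linearly interpolated across
#' circular gaps of at most `max_gap_deg`; wider gaps mark the profile
#' incomplete.
#'
#' @param trials A `trial_phase_amp` data frame.
#' @param labels Amplitude labels from [amplitude_split()].
#' @param max_gap_deg Maximum interpolatable run of empty centers.
#' @return Object of class `phase_profile`: list with numeric(360)
#'   `high` and `low` (index i is center i-1 degrees), `overall_or`,
#'   `n_retained`, and logical `complete` per level.
#' @export
rotating_profile <- function(trials, labels, max_gap_deg = 5) {
  keep <- !trials$rejected_asynchrony
  overall <- 100 * mean(trials$observed[keep])
  out <- list(overall_or = overall, n_retained = sum(keep),
              complete = c(low = TRUE, high = TRUE))
  for (lev in c("low", "high")) {
    sel <- keep & labels == lev
    sel[is.na(sel)] <- FALSE
    ph <- trials$combined_phase[sel]
    ob <- trials$observed[sel]
    vals <- rep(NA_real_, 360)
    for (c0 in 0:359) {
      inbin <- ((ph - (c0 - 45)) %% 360) < 90
      if (any(inbin)) vals[c0 + 1] <- 100 * mean(ob[inbin]) - overall
    }
    gap <- is.na(vals)
    if (any(gap)) {
      filled <- interp_circular_gaps(vals, max_gap_deg)
      if (anyNA(filled)) out$complete[lev] <- FALSE
      vals <- filled
    }
    out[[lev]] <- vals
  }
  class(out) <- "phase_profile"
  out
}

# Linear interpolation across circular runs of NA no longer than
# max_gap; longer runs stay NA.
interp_circular_gaps <- function(vals, max_gap) {
  n <- length(vals)
  na <- which(is.na(vals))
  if (!length(na) || length(na) == n) return(vals)
  runs <- split(na, cumsum(c(1, diff(na) != 1)))
  # merge wrap-around run
  if (length(runs) > 1 && runs[[1]][1] == 1 &&
      runs[[length(runs)]][length(runs[[length(runs)]])] == n) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  for (r in runs) {
    if (length(r) > max_gap) next
    before <- (r[1] - 2) %% n + 1
    after <- (r[length(r)]) %% n + 1
    m <- length(r) + 1
    for (k in seq_along(r))
      vals[r[k]] <- vals[before] + (vals[after] - vals[before]) * k / m
  }
  vals
}

#' Preferred phase of a delta-OR profile
#'
#' The direction toward the profile's center of mass:
#' `v = (1/360) * sum_c profile(c) * (cos c, sin c)`; the preferred
#' phase is the direction of `v` and the magnitude is `|v|` (the
#' center-of-mass offset, in delta-OR units).  The pessimal phase is the
#' opposite direction, and the preferred phase effect (PPE) is the
#' profile value at the preferred phase minus the value at the pessimal
#' phase, both read at the nearest integer degree.  For a cosine-shaped
#' profile `k*cos(c - a)` this gives angle `a`, magnitude `k/2`, and
#' PPE `2k`.
#'
#' @param profile Numeric vector of 360 delta-OR values (index i =
#'   center i-1 degrees), or a `phase_profile` plus `level`.
#' @param level When `profile` is a `phase_profile`: which amplitude
#'   level to use.
#' @return Object of class `preferred_phase`: `angle`, `magnitude`,
#'   `pessimal_angle`, `ppe` (all degrees / delta-OR units).
#' @export
preferred_phase <- function(profile, level = c("high", "low")) {
  if (inherits(profile, "phase_profile")) {
    level <- match.arg(level)
    profile <- profile[[level]]
  }
  if (length(profile) != 360) stop("profile must have 360 values")
  if (anyNA(profile)) stop("profile has undefined bins")
  cc <- (0:359) * pi / 180
  x <- mean(profile * cos(cc))
  y <- mean(profile * sin(cc))
  mag <- sqrt(x^2 + y^2)
  if (mag < 1e-12)
    stop("preferred phase undefined: zero center-of-mass vector")
  ang <- wrap_deg(atan2(y, x) * 180 / pi)
  structure(list(angle = ang, magnitude = mag,
                 pessimal_angle = wrap_deg(ang - 180),
                 ppe = profile_at(profile, ang) -
                   profile_at(profile, ang - 180)),
            class = "preferred_phase")
}

# Profile value at the nearest integer degree of a continuous angle.
profile_at <- function(profile, angle_deg) {
  profile[(round(angle_deg) %% 360) + 1]
}

#' @export
print.preferred_phase <- function(x, ...) {
  cat(sprintf(
    "<preferred_phase> %.2f deg (magnitude %.3f, PPE %.2f%%, pessimal %.2f deg)\n",
    x$angle, x$magnitude, x$ppe, x$pessimal_angle))
  invisible(x)
}

#' Group-level preferred phase
#'
#' Vector mean of the individual center-of-mass vectors (magnitude and
#' angle).  By linearity this equals the preferred phase of the
#' participant-averaged profile; when the individual `profiles` are
#' supplied the group PPE is read off that mean profile.
#'
#' @param individual List of [preferred_phase()] objects (>= 2).
#' @param profiles Optional list of the matching numeric(360) profiles;
#'   enables the group PPE.
#' @return A `preferred_phase` object (with `ppe = NA` if no profiles
#'   are given).
#' @export
group_preferred_phase <- function(individual, profiles = NULL) {
  if (length(individual) < 2) stop("need at least 2 individuals")
  ang <- vapply(individual, `[[`, numeric(1), "angle") * pi / 180
  mag <- vapply(individual, `[[`, numeric(1), "magnitude")
  x <- mean(mag * cos(ang)); y <- mean(mag * sin(ang))
  r <- sqrt(x^2 + y^2)
  if (r < 1e-12) stop("group preferred phase undefined: zero resultant")
  g_ang <- wrap_deg(atan2(y, x) * 180 / pi)
  ppe <- NA_real_
  if (!is.null(profiles)) {
    mp <- Reduce(`+`, profiles) / length(profiles)
    ppe <- profile_at(mp, g_ang) - profile_at(mp, g_ang - 180)
  }
  structure(list(angle = g_ang, magnitude = r,
                 pessimal_angle = wrap_deg(g_ang - 180), ppe = ppe),
            class = "preferred_phase")
}

#' Estimated angular confidence interval for the group preferred phase
#'
#' The individual preferred-phase vectors are converted to cartesian
#' coordinates; t-based confidence intervals are computed separately on
#' the x and y components; the returned angular interval is the set of
#' directions from the origin to the rectangle
#' `[x_lo, x_hi] x [y_lo, y_hi]` (the extreme directions are attained at
#' its corners).  If the rectangle contains the origin every direction
#' is possible and the full circle `[0, 360)` is returned with a
#' warning.
#'
#' @param individual List of [preferred_phase()] objects (>= 3).
#' @param level Confidence level (default 0.95).
#' @return List: `ci_deg` (length-2, degrees, the arc from `ci_deg[1]`
#'   counter-clockwise to `ci_deg[2]` containing the group angle),
#'   `full_circle` flag, and the component intervals `x_ci`, `y_ci`.
#' @export
preferred_phase_ci <- function(individual, level = 0.95) {
  if (length(individual) < 3) stop("need at least 3 individuals")
  ang <- vapply(individual, `[[`, numeric(1), "angle") * pi / 180
  mag <- vapply(individual, `[[`, numeric(1), "magnitude")
  xs <- mag * cos(ang); ys <- mag * sin(ang)
  n <- length(xs)
  tcrit <- stats::qt(1 - (1 - level) / 2, n - 1)
  x_ci <- mean(xs) + c(-1, 1) * tcrit * stats::sd(xs) / sqrt(n)
  y_ci <- mean(ys) + c(-1, 1) * tcrit * stats::sd(ys) / sqrt(n)
  if (x_ci[1] <= 0 && x_ci[2] >= 0 && y_ci[1] <= 0 && y_ci[2] >= 0) {
    warning("confidence rectangle contains the origin: full-circle CI")
    return(list(ci_deg = c(0, 360), full_circle = TRUE,
                x_ci = x_ci, y_ci = y_ci))
  }
  g_ang <- atan2(mean(ys), mean(xs)) * 180 / pi
  corners <- rbind(c(x_ci[1], y_ci[1]), c(x_ci[1], y_ci[2]),
                   c(x_ci[2], y_ci[1]), c(x_ci[2], y_ci[2]))
  offs <- circ_diff(atan2(corners[, 2], corners[, 1]) * 180 / pi, g_ang)
  lo <- wrap_deg(g_ang + min(offs))
  hi <- wrap_deg(g_ang + max(offs))
  list(ci_deg = c(lo, hi), full_circle = FALSE, x_ci = x_ci, y_ci = y_ci)
}
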