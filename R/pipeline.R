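#' Analyze one participant's recording at a measurement time
#'
#' The full single-participant chain of the detection task: zero-phase
#' 0.01-50 Hz band-pass on the continuous recording, averaged-mastoid
#' re-reference, down-sampling to the analysis rate (512 Hz) when
#' recorded faster, LO/RO occipital pooling, 10-Hz complex Morlet
#' phase/amplitude extraction, per-trial read-out at
#' `onset + t_measure_ms`, hemispheric-asynchrony rejection, median
#' amplitude split, the 2 x 4 bin grid, the 1-degree rotating-bin
#' profile, and the per-level preferred phases.
#'
#' @param rec An [recording()] with the occipital six and mastoid
#'   channels.
#' @param events Event table with flash events (defaults to the
#'   recording's own).
#' @param t_measure_ms Measurement time relative to flash onset, ms
#'   (the participant's t2, or e.g. -100).
#' @param analysis_rate Analysis sampling rate, Hz.
#' @param wavelet_cycles Morlet cycle count.
#' @param alpha_freq Wavelet center frequency, Hz.
#' @return List of class `shutter_result`: `trials`, `labels`, `grid`,
#'   `profile`, `pp` (per-level [preferred_phase()]), `overall_or`,
#'   `n_retained`, `t_measure_ms`.
#' @export
analyze_recording <- function(rec, events = rec$events, t_measure_ms,
                              analysis_rate = 512, wavelet_cycles = 8 / 3,
                              alpha_freq = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  # referencing, pooling and the zero-phase band-pass are all linear
  # and time-invariant, so they commute: pool first, then filter only
  # the two pooled series
  rec <- rereference_mastoids(rec)
  pooled <- pool_occipital(rec)
  fs <- rec$sampling_rate
  lo_x <- bandpass_series(pooled$lo, fs)
  ro_x <- bandpass_series(pooled$ro, fs)
  if (fs > analysis_rate) {
    two <- resample_recording(
      recording(cbind(lo = lo_x, ro = ro_x), fs), analysis_rate)
    lo_x <- two$data[, "lo"]; ro_x <- two$data[, "ro"]
    fs <- analysis_rate
  }
  kern <- morlet_wavelet(alpha_freq, wavelet_cycles, fs)
  lo <- wavelet_transform(lo_x, kern)
  ro <- wavelet_transform(ro_x, kern)
  trials <- trial_measures(lo, ro, events, t_measure_ms)
  labels <- amplitude_split(trials)
  grid <- bin_grid(trials, labels)
  profile <- rotating_profile(trials, labels)
  pp <- list()
  for (lev in c("high", "low"))
    pp[[lev]] <- if (profile$complete[lev])
      preferred_phase(profile, lev) else NULL
  structure(list(trials = trials, labels = labels, grid = grid,
                 profile = profile, pp = pp,
                 overall_or = attr(grid, "overall_or"),
                 n_retained = sum(!trials$rejected_asynchrony),
                 t_measure_ms = t_measure_ms),
            class = "shutter_result")
}

#' Simulate a cohort of shutter-task participants
#'
#' Expands one base [shutter_config()] into per-participant configs:
#' each participant gets an independent seed sub-stream, a conduction
#' delay drawn uniformly from `t2_range_ms`, and a mild log-normal
#' jitter of the alpha envelope mean (between-subject amplitude
#' variation).  The embedded preferred phase and gating depth are common
#' to the cohort (the group-level effect under test).
#'
#' @param n_participants Cohort size.
#' @param config Base [shutter_config()].
#' @param t2_range_ms Range of individual conduction delays, ms.
#' @param envelope_jitter_sd Sd of the log-scale envelope-mean jitter.
#' @param seed Cohort seed.
#' @return List of `shutter_config` objects with a `true_t2` each.
#' @export
simulate_cohort <- function(n_participants = 20,
                            config = shutter_config(),
                            t2_range_ms = c(63, 89),
                            envelope_jitter_sd = 0.15, seed = 1) {
  set.seed(seed)
  t2s <- stats::runif(n_participants, t2_range_ms[1], t2_range_ms[2])
  env_mult <- exp(stats::rnorm(n_participants, 0, envelope_jitter_sd))
  seeds <- sample.int(2^30, n_participants)
  lapply(seq_len(n_participants), function(i) {
    cfg <- config
    cfg$true_t2 <- t2s[i]
    cfg$envelope_mean <- config$envelope_mean * env_mult[i]
    cfg$envelope_sd <- config$envelope_sd * env_mult[i]
    cfg$seed <- seeds[i]
    cfg
  })
}

#' Run the simulate-analyze-test pipeline on a synthetic cohort
#'
#' Generates each participant's recording with
#' [gen_shutter_recording()], analyzes it with [analyze_recording()] at
#' the requested measurement time, assembles the cohort delta-OR table,
#' and runs the statistical battery: the two-way within-subject ANOVA
#' with Mauchly tests, Tukey HSD between phase bins within each
#' amplitude level, Bonferroni one-sample t tests against zero, and the
#' group preferred phase with its estimated angular CI per amplitude
#' level.
#'
#' Participants with an empty grid cell are excluded from the ANOVA and
#' post hoc tables (recorded in `excluded`); participants whose
#' rotating profile has non-interpolatable gaps are excluded from the
#' group preferred phase.
#'
#' @param cohort List of per-participant `shutter_config`s, e.g. from
#'   [simulate_cohort()].
#' @param t_measure `"t2"` (each participant's embedded conduction
#'   delay) or a numeric time in ms (e.g. `-100`).
#' @param min_participants Abort if fewer complete participants remain.
#' @param keep_participants If TRUE, the per-participant
#'   `shutter_result`s are kept in the output (memory-heavy).
#' @return List of class `shutter_pipeline`: `delta_or` (n x 2 x 4
#'   array), `anova`, `tukey` (per level), `t_tests`, `group_pp` and
#'   `group_ci` (per level), `participants` summary data frame,
#'   `excluded`, and optionally `results`.
#' @export
run_pipeline <- function(cohort, t_measure = "t2",
                         min_participants = 2,
                         keep_participants = FALSE) {
  n <- length(cohort)
  results <- vector("list", n)
  summaries <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- cohort[[i]]
    sim <- gen_shutter_recording(cfg)
    tm <- if (identical(t_measure, "t2")) cfg$true_t2 else t_measure
    res <- analyze_recording(sim$recording, sim$events, t_measure_ms = tm)
    summaries[[i]] <- data.frame(
      participant = i, t_measure_ms = tm, true_t2_ms = cfg$true_t2,
      n_trials = cfg$n_trials, n_retained = res$n_retained,
      overall_or = res$overall_or)
    results[[i]] <- res
  }
  assemble_group(results, do.call(rbind, summaries),
                 min_participants, keep_participants)
}

# Group-level statistics over a list of per-participant shutter_results.
assemble_group <- function(results, participants, min_participants = 2,
                           keep_participants = FALSE) {
  n <- length(results)
  centers <- c(0, 90, 180, 270)
  delta <- array(NA_real_, c(n, 2, 4),
                 dimnames = list(NULL, c("low", "high"), centers))
  for (i in seq_len(n)) {
    g <- results[[i]]$grid
    for (a in c("low", "high")) for (k in seq_along(centers)) {
      v <- g$delta_or[g$amplitude == a & g$phase_center == centers[k]]
      delta[i, a, k] <- v
    }
  }
  complete <- apply(delta, 1, function(x) !anyNA(x))
  excluded <- which(!complete)
  if (sum(complete) < min_participants)
    stop("too few participants with complete bin grids")
  dc <- delta[complete, , , drop = FALSE]
  anova <- rm_anova(dc)
  tukey <- list(high = tukey_phase_bins(dc, "high"),
                low = tukey_phase_bins(dc, "low"))
  cells <- matrix(dc, dim(dc)[1], 8)
  colnames(cells) <- paste(rep(c("low", "high"), 4),
                           rep(centers, each = 2), sep = "_")
  t_tests <- one_sample_t_bonferroni(cells, m = 8)
  group_pp <- list(); group_ci <- list()
  for (lev in c("high", "low")) {
    pps <- lapply(results, function(r) r$pp[[lev]])
    ok <- !vapply(pps, is.null, logical(1))
    if (sum(ok) >= 2) {
      profs <- lapply(results[ok], function(r) r$profile[[lev]])
      group_pp[[lev]] <- group_preferred_phase(pps[ok], profs)
      group_ci[[lev]] <- if (sum(ok) >= 3)
        preferred_phase_ci(pps[ok]) else NULL
    }
  }
  out <- list(delta_or = delta, anova = anova, tukey = tukey,
              t_tests = t_tests, group_pp = group_pp,
              group_ci = group_ci, participants = participants,
              excluded = excluded)
  if (keep_participants) out$results <- results
  structure(out, class = "shutter_pipeline")
}

#' @export
print.shutter_pipeline <- function(x, ...) {
  cat(sprintf("<shutter_pipeline> %d participants (%d excluded)\n",
              nrow(x$participants), length(x$excluded)))
  print(x$anova)
  for (lev in names(x$group_pp)) {
    pp <- x$group_pp[[lev]]
    ci <- x$group_ci[[lev]]
    cat(sprintf("  %s-amplitude preferred phase %.2f deg, PPE %.2f%%",
                lev, pp$angle, pp$ppe))
    if (!is.null(ci) && !ci$full_circle)
      cat(sprintf(", 95%% CI [%.2f, %.2f] deg", ci$ci_deg[1],
                  ci$ci_deg[2]))
    cat("\n")
  }
  invisible(x)
}

#' Write pipeline results to CSV/JSON files
#'
#' Emits `delta_or.csv` (participant x cell table), `anova.csv`,
#' `tukey_<level>.csv`, `t_tests.csv`, `profiles.csv` when
#' per-participant results were kept, `preferred_phase.json`, and
#' `run_info.json` (parameter echo).  All angles are degrees in
#' `[0, 360)` with the 90-degrees-equals-peak convention.
#'
#' @param x A `shutter_pipeline` result.
#' @param dir Output directory (created if needed).
#' @param run_info Optional named list echoed into `run_info.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_results <- function(x, dir, run_info = list()) {
  stopifnot(inherits(x, "shutter_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  dd <- as.data.frame.table(x$delta_or, responseName = "delta_or")
  names(dd) <- c("participant", "amplitude", "phase_center_deg",
                 "delta_or")
  wr(dd, "delta_or.csv")
  wr(x$anova$effects, "anova.csv")
  for (lev in names(x$tukey)) wr(x$tukey[[lev]],
                                 sprintf("tukey_%s.csv", lev))
  wr(x$t_tests, "t_tests.csv")
  pp <- lapply(names(x$group_pp), function(lev) {
    p <- x$group_pp[[lev]]
    ci <- x$group_ci[[lev]]
    list(amplitude_level = lev, angle_deg = p$angle,
         magnitude = p$magnitude, ppe_pct = p$ppe,
         pessimal_deg = p$pessimal_angle,
         ci_deg = if (!is.null(ci)) ci$ci_deg else NULL,
         phase_convention = "degrees in [0,360), 90 = peak")
  })
  ppf <- file.path(dir, "preferred_phase.json")
  jsonlite::write_json(pp, ppf, auto_unbox = TRUE, digits = NA)
  rif <- file.path(dir, "run_info.json")
  jsonlite::write_json(c(list(package = "alphashutter",
                              version = "0.1.0",
                              n_participants = nrow(x$participants),
                              excluded = x$excluded),
                         run_info),
                       rif, auto_unbox = TRUE, digits = NA)
  invisible(c(files, ppf, rif))
}
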