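#' Configuration for the synthetic checkerboard VEP generator
#'
#' Defaults mirror the conduction-delay estimation task: 600 upper- and
#' 600 lower-field checkerboard flashes in mixed random order with
#' 250-450 ms inter-stimulus intervals at 2048 Hz, carrying
#' opposite-polarity C1 deflections (negative for upper-field stimuli,
#' positive for lower-field) peaking 75 ms after onset at POz.
#'
#' @param n_upper,n_lower Trial counts per field; must be positive.
#' @param c1_peak_latency C1 peak latency in ms, inside `(0, 110)`.
#' @param c1_amplitude Absolute C1 amplitude in uV (applied negative for
#'   upper-field and positive for lower-field epochs).
#' @param c1_width FWHM of the Gaussian C1 deflection, ms.
#' @param blink_rate Per-epoch probability of a blink artifact.
#' @param blink_amplitude Blink size on the vEOG derivation, uV
#'   (peak-to-peak in a 150-ms window exceeds 100 uV at the default).
#' @param noise_scale Background 1/f noise sd per channel, uV (0 gives
#'   a noiseless construction).
#' @param noise_exponent Spectral slope of the background noise.
#' @param sampling_rate Hz.
#' @param inter_stimulus_interval_range Uniform ISI range in s.
#' @param pad_s Quiet padding at both ends, s.
#' @param seed Master RNG seed.
#' @return A validated `vep_config` list.
#' @export
vep_config <- function(n_upper = 600, n_lower = 600,
                       c1_peak_latency = 75, c1_amplitude = 4,
                       c1_width = 30, blink_rate = 0.05,
                       blink_amplitude = 150, noise_scale = 5,
                       noise_exponent = 1, sampling_rate = 2048,
                       inter_stimulus_interval_range = c(0.25, 0.45),
                       pad_s = 2, seed = 1) {
  cfg <- as.list(environment())
  if (n_upper < 1 || n_lower < 1) stop("trial counts must be positive")
  if (c1_peak_latency <= 0 || c1_peak_latency >= 110)
    stop("c1_peak_latency must lie in (0, 110) ms")
  if (blink_rate < 0 || blink_rate > 1) stop("blink_rate must be in [0, 1]")
  structure(cfg, class = "vep_config")
}

#' Generate a synthetic checkerboard VEP recording
#'
#' Builds a continuous recording with channels POz, Fp1/Fp2, IO1/IO2 and
#' M1/M2.  Each stimulus adds a Gaussian C1 deflection at POz (negative
#' for upper-field, positive for lower-field stimuli) peaking at the
#' configured latency; a configurable fraction of epochs carries a blink
#' artifact on the frontal/infraorbital channels whose vEOG derivation
#' exceeds 100 uV peak-to-peak.  Deterministic in `(config, seed)`.
#'
#' @param config A [vep_config()].
#' @return List with `recording` and `events` (types `upper`/`lower`).
#' @export
gen_vep_recording <- function(config) {
  stopifnot(inherits(config, "vep_config"))
  fs <- config$sampling_rate
  n_tr <- config$n_upper + config$n_lower

  set.seed(substream_seed(config$seed, "schedule"))
  isi <- stats::runif(n_tr, config$inter_stimulus_interval_range[1],
                      config$inter_stimulus_interval_range[2])
  onsets <- config$pad_s + cumsum(isi)
  types <- sample(rep(c("upper", "lower"),
                      c(config$n_upper, config$n_lower)))
  dur <- onsets[n_tr] + config$pad_s
  n <- as.integer(ceiling(dur * fs))

  chans <- c("POz", "Fp1", "Fp2", "IO1", "IO2", "M1", "M2")
  dat <- matrix(0, n, length(chans), dimnames = list(NULL, chans))

  # C1 deflections at POz
  w_s <- config$c1_width / 2.354820045 / 1000      # FWHM -> Gaussian sd, s
  lat_s <- config$c1_peak_latency / 1000
  bump_rel <- seq(as.integer(round((lat_s - 4 * w_s) * fs)),
                  as.integer(round((lat_s + 4 * w_s) * fs)))
  bump_t <- bump_rel / fs
  bump <- exp(-(bump_t - lat_s)^2 / (2 * w_s^2))
  for (i in seq_len(n_tr)) {
    sgn <- if (types[i] == "upper") -1 else 1
    idx <- time_to_sample(onsets[i], fs) + bump_rel
    dat[idx, "POz"] <- dat[idx, "POz"] + sgn * config$c1_amplitude * bump
  }

  # blink artifacts: Gaussian deflections opposite in sign above/below
  # the eye, so the bipolar vEOG derivation recovers the full amplitude
  set.seed(substream_seed(config$seed, "blinks"))
  has_blink <- stats::runif(n_tr) < config$blink_rate
  blink_center <- stats::runif(n_tr, -0.03, 0.12)   # s, relative to onset
  b_w <- 0.040                                      # blink sd, s
  b_rel <- seq(as.integer(round(-3 * b_w * fs)),
               as.integer(round(3 * b_w * fs)))
  b_shape <- exp(-(b_rel / fs)^2 / (2 * b_w^2))
  for (i in which(has_blink)) {
    idx <- time_to_sample(onsets[i] + blink_center[i], fs) + b_rel
    ok <- idx >= 1 & idx <= n
    idx <- idx[ok]
    sh <- b_shape[ok]
    amp <- config$blink_amplitude
    for (ch in c("Fp1", "Fp2")) dat[idx, ch] <- dat[idx, ch] + 0.6 * amp * sh
    for (ch in c("IO1", "IO2")) dat[idx, ch] <- dat[idx, ch] - 0.4 * amp * sh
  }

  if (config$noise_scale > 0) {
    set.seed(substream_seed(config$seed, "noise"))
    gain <- c(1, 1, 1, 1, 1, 0.3, 0.3)
    noise <- pink_noise_matrix(n, length(chans), config$noise_exponent)
    dat <- dat + noise %*% diag(config$noise_scale * gain)
  }

  events <- event_table(data.frame(onset = onsets, type = types,
                                   observed = NA))
  list(recording = recording(dat, fs, events), events = events)
}
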