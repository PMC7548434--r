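# Synthetic generators share a master seed expanded into named
# sub-streams so that e.g. the behavioral draws can be varied while the
# EEG noise is held fixed.
substream_seed <- function(seed, stream) {
  offs <- c(schedule = 101L, phase = 211L, envelope = 307L, noise = 401L,
            behavior = 503L, blinks = 601L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 1009 + offs[[stream]]) %% 2147483647)
}

# k columns of unit-sd 1/f^exponent noise of length n, via random-phase
# spectral shaping (computed at a power-of-two length, one batched
# inverse FFT, then truncated).
pink_noise_matrix <- function(n, k, exponent = 1) {
  m <- stats::nextn(n, 2)
  fbin <- pmin(0:(m - 1), m - (0:(m - 1)))
  amp <- c(0, fbin[-1]^(-exponent / 2))
  # batch columns per FFT call, but cap the working set for long n
  chunk <- max(1L, min(k, as.integer(2^23 / m)))
  x <- matrix(0, n, k)
  done <- 0L
  while (done < k) {
    kk <- min(chunk, k - done)
    z <- matrix(stats::rnorm(2 * m * kk), m, 2L * kk)
    spec <- amp * (z[, seq_len(kk), drop = FALSE] +
                   1i * z[, kk + seq_len(kk), drop = FALSE])
    x[, done + seq_len(kk)] <-
      Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
    done <- done + kk
  }
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

pink_noise <- function(n, exponent = 1) {
  pink_noise_matrix(n, 1L, exponent)[, 1]
}

# Slow (<cutoff Hz) unit-variance Gaussian process of length n.
slow_gaussian <- function(n, fs, cutoff) {
  b <- signal::butter(2, min(cutoff / (fs / 2), 0.99), type = "low")
  z <- signal::filtfilt(b, stats::rnorm(n + 2L * fs)) # pad against edges
  z <- z[(fs + 1L):(fs + n)]
  (z - mean(z)) / stats::sd(z)
}

#' Configuration for the synthetic shutter recording generator
#'
#' Defaults reproduce the study conditions of the main detection task:
#' 160 near-threshold flashes at a mean inter-stimulus interval of
#' 12.5 s, occipital 10-Hz alpha with a slowly varying log-normal
#' peak-to-peak envelope (mean 10 uV, sd 4 uV) over 1/f background
#' noise, an overall observation rate of 0.58, and phase-dependent
#' gating of depth 0.15 at a preferred (trough) phase of 270 degrees
#' read out 75 ms after stimulus onset, with the gating depth scaling
#' with the normalized envelope.
#'
#' @param sampling_rate Hz; must exceed `2 * alpha_freq`.
#' @param n_trials Number of flash trials.
#' @param alpha_freq Alpha oscillator frequency in Hz.
#' @param envelope_mean,envelope_sd Mean/sd of the log-normal
#'   peak-to-peak envelope, uV.
#' @param envelope_cutoff Low-pass cutoff of the envelope process, Hz.
#' @param freq_jitter_sd Sd of the slow random walk of instantaneous
#'   frequency, Hz (phase diffusion; 0 gives a stationary oscillator).
#' @param freq_jitter_tau Correlation time of the frequency jitter, s.
#' @param noise_exponent Spectral slope of the 1/f background.
#' @param noise_scale Background noise sd per occipital channel, uV.
#' @param true_t2 Conduction delay at which the gating phase is read,
#'   ms after flash onset.
#' @param true_preferred_phase Phase (degrees, 90 = peak convention) at
#'   which observation probability is maximal.
#' @param base_rate Baseline observation probability.
#' @param gating_depth Amplitude of the cosine modulation of observation
#'   probability (probability units).
#' @param amplitude_gating If TRUE, per-trial depth scales with the
#'   envelope normalized by its median across trials.
#' @param inter_stimulus_interval_range Length-2 numeric, uniform ISI
#'   range in s.
#' @param max_clamp_frac Error if more than this fraction of trial
#'   probabilities had to be clamped into `[0, 1]`.
#' @param pad_s Quiet padding at both ends of the recording, s.
#' @param seed Master RNG seed.
#' @return A validated `shutter_config` list.
#' @export
shutter_config <- function(sampling_rate = 512, n_trials = 160,
                           alpha_freq = 10, envelope_mean = 10,
                           envelope_sd = 4, envelope_cutoff = 1,
                           freq_jitter_sd = 0.3, freq_jitter_tau = 1,
                           noise_exponent = 1, noise_scale = 4,
                           true_t2 = 75, true_preferred_phase = 270,
                           base_rate = 0.58, gating_depth = 0.15,
                           amplitude_gating = TRUE,
                           inter_stimulus_interval_range = c(10.5, 14.5),
                           max_clamp_frac = 0.2, pad_s = 3, seed = 1) {
  cfg <- as.list(environment())
  if (sampling_rate <= 2 * alpha_freq)
    stop("sampling_rate must exceed twice alpha_freq")
  if (true_preferred_phase < 0 || true_preferred_phase >= 360)
    stop("true_preferred_phase must lie in [0, 360)")
  if (base_rate < 0 || base_rate > 1) stop("base_rate must be in [0, 1]")
  if (gating_depth < 0) stop("gating_depth must be non-negative")
  if (n_trials < 1) stop("n_trials must be positive")
  isr <- inter_stimulus_interval_range
  if (length(isr) != 2 || isr[1] <= 0 || isr[2] < isr[1])
    stop("inter_stimulus_interval_range must be increasing and positive")
  structure(cfg, class = "shutter_config")
}

#' Generate a synthetic recording with an embedded shutter effect
#'
#' Synthesizes a multichannel recording (occipital six, POz, Fp1/Fp2,
#' infraorbitals IO1/IO2, mastoids M1/M2) in which both hemispheres
#' share one 10-Hz alpha source -- a slowly drifting-phase oscillator
#' multiplied by a low-pass-filtered log-normal envelope -- plus
#' hemisphere-shared and channel-independent 1/f noise, so that pooled
#' LO/RO phases agree within the 90-degree asynchrony criterion on most
#' trials.  Flash events are scheduled uniformly within the configured
#' ISI range; each trial's observation outcome is a Bernoulli draw of
#'
#' `p = clamp(base_rate + depth_i * cos(phase_i - true_preferred_phase))`
#'
#' where `phase_i` is the oscillator's true phase (90 = peak convention)
#' at the sample nearest `onset + true_t2` and `depth_i` scales with the
#' normalized envelope when `amplitude_gating` is on.
#'
#' The generator is a pure function of its config: the same seed
#' reproduces the outputs bit for bit.
#'
#' @param config A [shutter_config()].
#' @return List with `recording` (an [recording()] with the event table
#'   attached), `events` (flash and response events), and `truth`, a
#'   data frame per trial: `trial, onset_s, true_phase_deg, envelope_uv,
#'   p_observe, observed` (the ground truth for recovery tests).
#' @export
gen_shutter_recording <- function(config) {
  stopifnot(inherits(config, "shutter_config"))
  fs <- config$sampling_rate

  set.seed(substream_seed(config$seed, "schedule"))
  isi <- stats::runif(config$n_trials,
                      config$inter_stimulus_interval_range[1],
                      config$inter_stimulus_interval_range[2])
  onsets <- config$pad_s + cumsum(isi)
  dur <- onsets[length(onsets)] + config$pad_s
  n <- as.integer(ceiling(dur * fs))

  # alpha source: drifting-phase oscillator x slow log-normal envelope
  set.seed(substream_seed(config$seed, "phase"))
  theta0 <- stats::runif(1, 0, 2 * pi)
  if (config$freq_jitter_sd > 0) {
    rho <- 1 - 1 / (config$freq_jitter_tau * fs)
    innov_sd <- config$freq_jitter_sd * sqrt(1 - rho^2)
    jit <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                                    method = "recursive"))
  } else jit <- numeric(n)
  theta <- theta0 + 2 * pi * cumsum(config$alpha_freq + jit) / fs

  set.seed(substream_seed(config$seed, "envelope"))
  z <- slow_gaussian(n, fs, config$envelope_cutoff)
  cv2 <- (config$envelope_sd / config$envelope_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(config$envelope_mean) - sdlog^2 / 2
  env <- exp(meanlog + sdlog * z)          # peak-to-peak envelope, uV
  alpha <- (env / 2) * cos(theta)

  set.seed(substream_seed(config$seed, "noise"))
  chans <- c("O1", "PO3", "PO7", "O2", "PO4", "PO8", "POz",
             "Fp1", "Fp2", "IO1", "IO2", "M1", "M2")
  alpha_gain <- c(1, 1, 1, 1, 1, 1, 0.8, 0.15, 0.15, 0.05, 0.05, 0, 0)
  noise_gain <- c(rep(1, 7), 1, 1, 1, 1, 0.3, 0.3)
  hemi <- c("L", "L", "L", "R", "R", "R", NA, NA, NA, NA, NA, NA, NA)
  noise <- pink_noise_matrix(n, length(chans) + 2L, config$noise_exponent)
  hemi_noise <- list(L = noise[, length(chans) + 1L],
                     R = noise[, length(chans) + 2L])
  w_shared <- sqrt(0.5)
  dat <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (j in seq_along(chans)) {
    shared <- if (!is.na(hemi[j])) hemi_noise[[hemi[j]]] else 0
    dat[, j] <- alpha_gain[j] * alpha + config$noise_scale * noise_gain[j] *
      (w_shared * shared +
         sqrt(1 - w_shared^2 * !is.na(hemi[j])) * noise[, j])
  }

  # behavior: outcome drawn from the true phase at onset + t2
  t2_samp <- as.integer(round(config$true_t2 / 1000 * fs))
  idx <- time_to_sample(onsets, fs) + t2_samp
  true_phase <- wrap_deg(theta[idx] * 180 / pi + 90)
  env_i <- env[idx]
  depth <- if (config$amplitude_gating) {
    config$gating_depth * env_i / stats::median(env_i)
  } else rep(config$gating_depth, length(idx))
  p_raw <- config$base_rate +
    depth * cos((true_phase - config$true_preferred_phase) * pi / 180)
  p <- pmin(pmax(p_raw, 0), 1)
  clamped <- mean(p != p_raw)
  if (clamped > config$max_clamp_frac)
    stop(sprintf(paste0("mis-specified config: %.0f%% of trial ",
                        "probabilities left [0, 1] (max allowed %.0f%%)"),
                 100 * clamped, 100 * config$max_clamp_frac))

  set.seed(substream_seed(config$seed, "behavior"))
  observed <- stats::runif(length(p)) < p
  resp_lat <- stats::runif(length(p), 0.3, 1.2)

  flash <- data.frame(onset = onsets, type = "flash", observed = observed,
                      response_s = ifelse(observed, resp_lat, NA_real_))
  resp <- data.frame(onset = onsets[observed] + resp_lat[observed],
                     type = "response", observed = NA,
                     response_s = NA_real_)
  events <- event_table(rbind(flash, resp)[order(c(onsets,
                                                   resp$onset)), ])
  rownames(events) <- NULL

  truth <- data.frame(trial = seq_along(onsets), onset_s = onsets,
                      true_phase_deg = true_phase, envelope_uv = env_i,
                      p_observe = p, observed = observed)
  list(recording = recording(dat, fs, events), events = events,
       truth = truth)
}
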