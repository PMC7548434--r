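#' Construct a complex Morlet wavelet kernel
#'
#' The kernel is a complex exponential at `center_freq` under a Gaussian
#' envelope with `sigma_t = n_cycles / (2 * pi * center_freq)`.  The
#' default 2 2/3 cycles at 10 Hz trades spectral for temporal
#' resolution: it behaves as a band-pass covering roughly the alpha band
#' (half-power points near 5.6 and 14.4 Hz) while keeping the temporal
#' smoothing window near 100 ms.
#'
#' The support is truncated at `+/- 3 sigma_t` (floored to the sample
#' grid, odd tap count; the envelope is about 1.1% of its maximum at the
#' edges).  Taps are normalized so that convolving a unit-amplitude
#' sinusoid at `center_freq` yields an analytic envelope of 1, hence a
#' peak-to-peak amplitude readout of 2.
#'
#' @param center_freq Center frequency in Hz (default 10).
#' @param n_cycles Number of cycles in the Gaussian envelope
#'   (default `8/3`).
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @return An object of class `morlet_kernel` with complex `taps`,
#'   `times` (s), `sigma_t` (s), and the construction parameters.
#' @export
morlet_wavelet <- function(center_freq = 10, n_cycles = 8 / 3,
                           sampling_rate = 512) {
  if (center_freq <= 0 || n_cycles <= 0 || sampling_rate <= 0)
    stop("morlet_wavelet parameters must be positive")
  sigma_t <- n_cycles / (2 * pi * center_freq)
  half <- as.integer(floor(3 * sigma_t * sampling_rate))
  t <- (-half:half) / sampling_rate
  env <- exp(-t^2 / (2 * sigma_t^2))
  taps <- (2 / sum(env)) * env * exp(2i * pi * center_freq * t)
  structure(list(
    taps = taps, times = t, sigma_t = sigma_t,
    center_freq = center_freq, n_cycles = n_cycles,
    sampling_rate = sampling_rate
  ), class = "morlet_kernel")
}

#' @export
print.morlet_kernel <- function(x, ...) {
  cat(sprintf(
    "<morlet_kernel> %g Hz, %.4g cycles @ %g Hz (%d taps, sigma_t = %.2f ms)\n",
    x$center_freq, x$n_cycles, x$sampling_rate, length(x$taps),
    x$sigma_t * 1000))
  invisible(x)
}

# Centered same-length complex convolution via FFT.
conv_same <- function(x, taps) {
  n <- length(x); m <- length(taps)
  if (n <= m) stop("signal shorter than kernel support")
  nfft <- stats::nextn(n + m - 1L, 2)
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                     stats::fft(c(taps, rep(0, nfft - m))),
                     inverse = TRUE) / nfft
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

#' Convolve a signal with a Morlet kernel
#'
#' Returns the analytic (complex) series of the same length as the
#' input.  Samples within half the kernel support of either edge have
#' incomplete kernel overlap and are flagged in `edge`; phase or
#' amplitude read-outs there are unreliable and [trial_measures()]
#' refuses them.
#'
#' Phase is reported in the "90 degrees = peak" convention: the raw
#' convolution angle (0 at a cosine peak) is shifted by +90 degrees so
#' that a sinusoid's peak maps to 90, its trough to 270, and its
#' ascending zero-crossing to 0.
#'
#' @param x Numeric signal (microvolts).
#' @param kernel A [morlet_wavelet()].
#' @return An object of class `analytic_series` with complex `values`,
#'   logical `edge`, and `sampling_rate`.
#' @export
wavelet_transform <- function(x, kernel) {
  stopifnot(inherits(kernel, "morlet_kernel"))
  values <- conv_same(as.numeric(x), kernel$taps)
  half <- (length(kernel$taps) - 1L) %/% 2L
  n <- length(values)
  edge <- logical(n)
  edge[seq_len(min(half, n))] <- TRUE
  edge[seq.int(max(1L, n - half + 1L), n)] <- TRUE
  structure(list(values = values, edge = edge,
                 sampling_rate = kernel$sampling_rate),
            class = "analytic_series")
}

#' Phase of an analytic series in degrees (90 = peak)
#' @param as An `analytic_series` (or complex vector).
#' @return Phase in degrees in `[0, 360)`.
#' @export
phase_deg <- function(as) {
  v <- if (inherits(as, "analytic_series")) as$values else as
  wrap_deg(Arg(v) * 180 / pi + 90)
}

#' Peak-to-peak amplitude of an analytic series
#'
#' Twice the square root of the power signal, i.e. `2 * Mod(values)`:
#' for a pure sinusoid of amplitude A this reads out `2A`, the
#' peak-to-peak excursion.
#'
#' @param as An `analytic_series` (or complex vector).
#' @return Peak-to-peak amplitude in microvolts.
#' @export
p2p_amplitude <- function(as) {
  v <- if (inherits(as, "analytic_series")) as$values else as
  2 * sqrt(Mod(v)^2)
}

#' Time-domain FWHM of a Morlet kernel
#'
#' Full width at half maximum of the sampled amplitude envelope.  The
#' half-maximum crossing on each side is rounded outward to the sample
#' grid (the first sample strictly below half maximum), so the width is
#' an integer number of sample periods.
#'
#' @param kernel A [morlet_wavelet()].
#' @return Width in ms.
#' @export
measure_fwhm_time <- function(kernel) {
  stopifnot(inherits(kernel, "morlet_kernel"))
  env <- Mod(kernel$taps)
  idx <- which(env >= max(env) / 2)
  lo <- max(min(idx) - 1L, 1L)
  hi <- min(max(idx) + 1L, length(env))
  (hi - lo) / kernel$sampling_rate * 1000
}

#' Spectral FWHM of a Morlet kernel
#'
#' Full width at half maximum of the amplitude spectrum of the sampled,
#' finite-support kernel, computed on a zero-padded FFT grid with linear
#' interpolation of the half-maximum crossings.  The finite (3 sigma)
#' support widens the spectrum slightly relative to the continuous-limit
#' Gaussian value `2 * sqrt(2 * log(2)) * center_freq / n_cycles`.
#'
#' @param kernel A [morlet_wavelet()].
#' @param nfft FFT length (default `2^16`).
#' @return List with `fwhm_hz` and the `half_power_hz` crossing pair.
#' @export
measure_fwhm_freq <- function(kernel, nfft = 2^16) {
  stopifnot(inherits(kernel, "morlet_kernel"))
  fs <- kernel$sampling_rate
  sp <- Mod(stats::fft(c(kernel$taps, rep(0, nfft - length(kernel$taps)))))
  freqs <- (0:(nfft - 1)) * fs / nfft
  keep <- freqs < fs / 2
  sp <- sp[keep]; freqs <- freqs[keep]
  m <- max(sp)
  above <- which(sp >= m / 2)
  lo_i <- min(above); hi_i <- max(above)
  cross <- function(i_out, i_in) {
    freqs[i_out] + (m / 2 - sp[i_out]) * (freqs[i_in] - freqs[i_out]) /
      (sp[i_in] - sp[i_out])
  }
  f_lo <- if (lo_i > 1) cross(lo_i - 1L, lo_i) else freqs[1]
  f_hi <- cross(hi_i + 1L, hi_i)
  list(fwhm_hz = f_hi - f_lo, half_power_hz = c(f_lo, f_hi))
}

#' Event-related percent amplitude change (ERD)
#'
#' Percent change of the trial-averaged alpha amplitude relative to a
#' prestimulus baseline: `100 * (A(t) - A_base) / A_base`, where `A(t)`
#' is the across-trials mean amplitude and `A_base` its mean over the
#' baseline window.  Negative values are event-related
#' desynchronization.
#'
#' @param amplitude_epochs Trial x time matrix of amplitude values.
#' @param time_ms Time axis in ms relative to stimulus onset.
#' @param baseline_ms Baseline window in ms (default `c(-300, -100)`).
#' @return Numeric vector, percent change per time sample.
#' @export
erd_percent <- function(amplitude_epochs, time_ms,
                        baseline_ms = c(-300, -100)) {
  amplitude_epochs <- as.matrix(amplitude_epochs)
  if (ncol(amplitude_epochs) != length(time_ms))
    stop("time axis does not match epochs")
  base_idx <- time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2]
  if (!any(base_idx)) stop("epochs do not cover the baseline window")
  avg <- colMeans(amplitude_epochs)
  base <- mean(avg[base_idx])
  if (base == 0) stop("zero baseline amplitude")
  100 * (avg - base) / base
}

#' Inter-trial phase coherence
#'
#' At each time sample, the resultant length of the across-trials mean
#' of unit phase vectors; 1 means identical phase in every trial, values
#' near `sqrt(pi) / (2 * sqrt(n))` are expected for n uniform phases.
#'
#' @param phase_epochs_deg Trial x time matrix of phases in degrees.
#' @return Numeric vector in `[0, 1]` per time sample.
#' @export
phase_coherence <- function(phase_epochs_deg) {
  phase_epochs_deg <- as.matrix(phase_epochs_deg)
  if (nrow(phase_epochs_deg) < 2)
    stop("phase coherence needs at least 2 trials")
  rad <- phase_epochs_deg * pi / 180
  Mod(colMeans(exp(1i * rad)))
}
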