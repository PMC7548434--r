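# Shared fixture builders: everything is generated in code at test time.

# Multichannel recording whose channels are given functions of time (or
# constants), plus optional events.
make_recording <- function(channel_funs, fs = 512, dur_s = 4,
                           events = NULL) {
  t <- (0:(dur_s * fs - 1)) / fs
  dat <- sapply(channel_funs, function(f) {
    if (is.function(f)) f(t) else rep_len(f, length(t))
  })
  colnames(dat) <- names(channel_funs)
  recording(dat, fs, events)
}

# Standard 13-channel zero recording used where content is irrelevant.
zero_recording <- function(fs = 512, dur_s = 4) {
  chans <- c("O1", "PO3", "PO7", "O2", "PO4", "PO8", "POz",
             "Fp1", "Fp2", "IO1", "IO2", "M1", "M2")
  funs <- stats::setNames(rep(list(0), length(chans)), chans)
  make_recording(funs, fs, dur_s)
}

# Analytic series with prescribed per-sample phase (deg, 90 = peak) and
# peak-to-peak amplitude, bypassing the wavelet (for exact-value tests).
make_analytic <- function(phase_deg, p2p, fs = 512) {
  structure(list(
    values = (p2p / 2) * exp(1i * (phase_deg - 90) * pi / 180),
    edge = rep(FALSE, length(phase_deg)),
    sampling_rate = fs
  ), class = "analytic_series")
}

# trial_phase_amp table straight from phases/amplitudes/outcomes
# (already "measured"; rejection recomputed from the LO/RO difference).
make_trials <- function(phase, amp, observed,
                        lo_phase = phase, ro_phase = phase) {
  rejected <- abs(circ_diff(lo_phase, ro_phase)) > 90
  out <- data.frame(
    trial = seq_along(phase),
    lo_phase = lo_phase, ro_phase = ro_phase,
    lo_amp = amp, ro_amp = amp,
    combined_phase = ifelse(rejected, NA_real_, phase),
    combined_amp = ifelse(rejected, NA_real_, amp),
    observed = observed,
    rejected_asynchrony = rejected
  )
  class(out) <- c("trial_phase_amp", "data.frame")
  out
}

# preferred_phase stub from an (angle, magnitude) pair.
make_pp <- function(angle, magnitude) {
  structure(list(angle = angle, magnitude = magnitude,
                 pessimal_angle = wrap_deg(angle - 180), ppe = NA_real_),
            class = "preferred_phase")
}

# Reduced-scale shutter config for fast end-to-end tests.
reduced_config <- function(...) {
  args <- list(sampling_rate = 256, n_trials = 40,
               inter_stimulus_interval_range = c(1.0, 1.3))
  over <- list(...)
  args[names(over)] <- over
  do.call(shutter_config, args)
}
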