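---
title: "Methods: conduction-delay-referenced alpha-phase analysis"
author: "alphashutter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conduction-delay-referenced alpha-phase analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphashutter)
```

## The question and the model

The posterior alpha rhythm (7--13 Hz, strongest over occipital cortex
with eyes closed) is widely interpreted as a signature of cycling
excitability in the thalamo-cortical visual relay: when relay cells are
collectively near their inhibited phase, a weak visual input is less
likely to be transmitted to V1 -- a periodic "shutter" on visual
transmission.  If that is right, whether an observer detects a
near-threshold flash should depend on the alpha *phase* at the moment
the flash's afferent volley reaches the thalamo-cortical stage, and the
dependence should be stronger when alpha *amplitude* is high (high
amplitude indicating more synchronous population cycling).

The critical methodological point is *when* to read the phase.  A flash
hits the retina at stimulus onset `t0`, but the EEG correlate of the
relevant excitability state is only measurable at the cortex after the
retina-to-V1 conduction delay, `t2`.  This package therefore reads
alpha phase and amplitude at `t0 + t2`, with `t2` estimated per
individual from the peak latency of the C1 component of the
visual-evoked potential (the earliest cortical deflection, which
inverts polarity between upper- and lower-visual-field stimuli because
of the cruciform folding of V1 around the calcarine fissure).

The package implements the full analysis as reusable modules and ships
a synthetic-EEG generator that embeds a known shutter effect, so every
stage -- filtering, pooling, wavelet phase extraction, trial rejection,
binning, circular summaries, and the repeated-measures statistics --
can be exercised end to end against ground truth.

## Pipeline stages

1. **Preprocessing.**  A second-order Butterworth band-pass
   (0.01--50 Hz) is applied forward and backward to the continuous
   recording, giving zero phase shift and -6 dB at the band edges
   (-3 dB per pass).  Recordings are re-referenced to averaged
   mastoids.  A bipolar vertical EOG is derived as mean(Fp1, Fp2) minus
   the mean of the infraorbital pair.  The detection-task chain is
   analyzed at 512 Hz (integer decimation with a protective zero-phase
   anti-alias filter); the C1 chain keeps the native rate.
2. **C1 / t2 estimation.**  Upper- and lower-field checkerboard epochs
   (-50 to 200 ms) are blink-screened by sliding a 150-ms window in
   75-ms steps over the vEOG epoch and rejecting any trial with a
   window peak-to-peak of 100 uV or more.  Accepted trials are
   averaged, baseline-corrected to the 50-ms prestimulus interval, and
   subtracted (upper minus lower) so the combined C1 deflection is
   negative; `t2` is the latency of the most negative sample in
   0--110 ms.
3. **Phase/amplitude extraction.**  Left- and right-occipital pools
   (LO = mean of O1, PO3, PO7; RO = mean of O2, PO4, PO8) are convolved
   with a 10-Hz complex Morlet wavelet of 2 2/3 cycles.  Phase uses the
   "90 degrees = peak" convention; peak-to-peak amplitude is twice the
   square root of power.
4. **Trial statistics.**  Per flash, phase and amplitude are read at
   `t0 + t2` (nearest sample).  Trials whose LO/RO phases differ by
   more than 90 degrees are rejected (hemispheric asynchrony); retained
   trials combine the two readings by two-point circular mean and
   arithmetic mean.  Trials are split at the per-participant median
   amplitude and into four 90-degree phase bins centered on 0, 90, 180
   and 270 degrees.  Each cell's observation rate (OR, percent
   observed) minus the overall OR gives delta-OR -- a difference in
   percentage points, not a ratio.
5. **Rotating-bin profile.**  The 90-degree bin is rotated in 1-degree
   steps, yielding a 360-point delta-OR profile per amplitude level.
   The *preferred phase* is the direction of the profile's center of
   mass, `v = (1/360) * sum_c profile(c) * (cos c, sin c)`; its
   magnitude is `|v|`; the *pessimal phase* is the opposite direction;
   and the *preferred phase effect* (PPE) is the profile value at the
   preferred phase minus the value at the pessimal phase.  For a
   cosine-shaped profile with amplitude `k`, the magnitude is `k/2` and
   the PPE is `2k` (so PPE = 4 x magnitude).
6. **Statistics.**  A 2 (amplitude) x 4 (phase) within-subject ANOVA on
   the delta-OR table, with Mauchly sphericity tests for the phase
   factor and the interaction (both chi-square on 5 df in this design),
   partial eta squared, and post hoc observed power; Tukey HSD between
   phase bins within each amplitude level; and Bonferroni-corrected
   one-sample t tests of each cell against zero.  Group preferred
   phases are vector means of the individual center-of-mass vectors
   (identical, by linearity, to the preferred phase of the averaged
   profile), with an angular confidence interval estimated from t-based
   CIs on the cartesian components.

## Wavelet characterization and its conventions

With `sigma_t = n_cycles / (2 pi f0)` (42.44 ms at 10 Hz and 8/3
cycles), the continuous-limit Gaussian FWHM values are
`2 sqrt(2 ln 2) sigma_t = 99.9 ms` and
`2 sqrt(2 ln 2) f0 / n_cycles = 8.83 Hz`.  The package characterizes
the *sampled, finite-support* kernel instead, under conventions it
states exactly:

* **Support.**  Taps cover `+/- 3 sigma_t`, floored to the sample grid
  (131 taps at 512 Hz; the envelope is ~1.1% of its maximum at the
  edges).  A tighter support than the usual 4--5 sigma was chosen
  deliberately: the mild spectral widening it induces is part of the
  kernel's effective band-pass characterization below.
* **Time-domain FWHM.**  The half-maximum crossings of the sampled
  envelope are rounded *outward* to the first sub-half-maximum sample
  on each side, so the width is an integer number of sample periods:
  52 samples = 101.56 ms at 512 Hz.
* **Spectral FWHM.**  The amplitude spectrum of the zero-padded kernel
  (FFT length 2^16) is interpolated linearly at its half-maximum
  crossings, giving 8.87 Hz with half-power points at 5.57 and
  14.43 Hz -- i.e. the convolution acts as a band-pass spanning
  approximately the alpha band.

```{r wavelet}
k <- morlet_wavelet(10, 8 / 3, 512)
measure_fwhm_time(k)
measure_fwhm_freq(k)$fwhm_hz
```

## What the synthetic generator emulates

`gen_shutter_recording()` synthesizes the channels the pipeline
consumes (the occipital six, POz, Fp1/Fp2, infraorbitals, mastoids).
Both hemispheres share one alpha source: a 10-Hz oscillator whose
instantaneous frequency follows a slow mean-reverting random walk
(phase diffusion), multiplied by a log-normal envelope low-pass
filtered below 1 Hz.  The log-normal, slowly varying envelope yields
unimodal, right-skewed per-trial amplitude distributions, and the phase
diffusion is what makes prestimulus (-100 ms) read-outs genuinely worse
than read-outs at `t2`.  On top of the shared source, each channel
carries 1/f background noise split into a hemisphere-shared and a
channel-independent part, so pooled LO/RO phases agree on most trials
but not identically.

Behavior is generated from the model under test: each trial's
observation outcome is a Bernoulli draw of

```
p = clamp(base_rate + depth_i * cos(phase_i - true_preferred_phase))
```

with `phase_i` the oscillator's true phase at `t0 + true_t2` and
`depth_i = gating_depth * envelope_i / median(envelope)` when amplitude
gating is on.  If more than a configured fraction of probabilities must
be clamped into [0, 1], the generator refuses the configuration as
mis-specified.

Defaults encode the detection-task conditions: 512 Hz, 160 trials at
10.5--14.5 s inter-stimulus intervals (mean 12.5 s), base rate 0.58,
preferred phase 270 degrees (the trough), gating depth 0.15, `true_t2`
75 ms, envelope mean 10 uV / sd 4 uV peak-to-peak, 1/f noise of 4 uV
per channel.  `simulate_cohort()` varies `t2` uniformly over 63--89 ms
and jitters the envelope scale across participants while keeping the
embedded effect common.

What the generator does **not** emulate: eye blinks and other artifacts
in the detection task (blinks are modeled only in the VEP generator,
where the rejection rule consumes them), evoked responses to the flash
(deliberately -- the induced-activity controls must come out flat),
individual alpha-frequency differences, non-sinusoidal alpha waveform
shape, volume-conduction channel correlations beyond the shared-source
structure, and experimenter-triggered stimulus timing (flashes are
scheduled uniformly within the configured ISI range).  Passing recovery
tests therefore show the pipeline is correct and sensitive under the
assumed signal model, not that real EEG satisfies that model.

The VEP generator embeds opposite-polarity Gaussian C1 deflections
(negative for upper-field stimuli) at a configurable latency on POz,
plus blink artifacts whose vEOG derivation exceeds the 100-uV rejection
threshold.  With the default 600 + 600 trials, the C1 latency is
recovered within two samples at 2048 Hz.

## Numerical and design choices

* **Epoch windows** are half-open in samples, `[onset + lo,
  onset + hi)`: a (-50, 200) ms window at 2048 Hz is exactly 512
  samples.  This avoids double-counting the endpoint and keeps epoch
  length proportional to the sampling rate.
* **Blink windows** start at the epoch's first sample and advance by
  the step; a final partial window is evaluated iff at least half the
  window length remains, so the epoch tail is covered.
* **Subtraction direction** for the difference wave is upper minus
  lower, making the combined C1 deflection negative so that "most
  negative peak" is well-posed; the opposite direction is available and
  yields the same latency.  Peak latency uses the raw minimum sample
  (no interpolation); ties break to the earliest sample.
* **Asynchrony rejection** is strict: exactly 90 degrees of LO/RO
  disagreement is retained.
* **Median split**: trials at the median go to the low-amplitude level;
  if all amplitudes are equal the split is degenerate (all low) and a
  warning is raised.  The median is computed on retained trials only,
  because rejection precedes binning.
* **Rotating-bin gaps**: at realistic trial counts every 90-degree bin
  is populated; if a center is empty the profile is interpolated
  linearly across circular gaps of at most 5 degrees, and wider gaps
  mark the participant's profile incomplete (excluded from group
  preferred-phase summaries).
* **Preferred-phase read-out** evaluates the profile at the nearest
  integer degree of the continuous center-of-mass angle.
* **Group aggregation** weights participants equally (not by trial
  count), matching the within-subject design; individual vectors enter
  the group mean with their center-of-mass magnitudes.  (PPE-weighted
  aggregation would be proportional for cosine-like profiles but not in
  general; center-of-mass weighting is the implemented definition.)
* **Angular CI**: the extreme directions from the origin to the
  cartesian confidence rectangle are attained at its corners, so the
  interval is computed from corner angles; a rectangle containing the
  origin returns the full circle with a warning.  The interval is not
  generally centered on the group angle.
* **Tukey error term**: the studentized-range test within one amplitude
  level uses the phase-by-subject mean square refit within that level
  (df = 57 for 20 participants), which matches the per-level reporting
  of the post hoc contrasts; pooling the omnibus error is available as
  an option.  One-sample t tests against zero use df = n - 1 = 19 and
  multiply p by the 8 comparisons.
* **Mauchly's statistic** uses the standard first-order chi-square
  approximation `-(n-1) d ln W`; the interaction test applies the
  Kronecker product of the two factors' orthonormal contrasts, giving
  5 df for the 2 x 4 design.
* **Observed power** uses the noncentral-F convention
  `lambda = F * df_num`, the convention under which the design's
  published-style power columns are reproducible from the F values
  alone.
* **p-values** are printed to four decimals and never as exactly zero.

## Problem sizes used by the test suite

The suite exercises the full study scale once -- a 20-participant
cohort of 160-trial recordings at the default 12.5-s ISI -- for the
parameter-recovery check (group preferred phase within 15 degrees of
the embedded 270 degrees, high-amplitude PPE above low-amplitude PPE,
significant phase and interaction effects).  The type-I calibration
uses 500 reduced cohorts (6 participants x 40 trials at 1.0--1.3-s ISI,
256 Hz), sizes chosen to make a 500-replicate null experiment practical
at a desk while leaving the per-cell trial counts large enough that
empty bins are rare; participants with an empty bin are excluded, as in
the analysis proper.  The C1 recovery tests run at the full 600 + 600
trials.  Oracle-equivalence tests (exhaustive recounts, brute-force
vector sums, reference implementations of the ANOVA family) run on
small randomized fixtures.

## Known limitations

* The pipeline fixes the wavelet at 10 Hz; observers whose alpha peaks
  far from 10 Hz are analyzed through the same 5.6--14.4 Hz band-pass,
  which dilutes phase estimates rather than adapting to the individual
  spectrum.
* The angular CI is an estimate built from componentwise t intervals;
  it has no exact coverage guarantee for directions of non-unit mean
  vectors, and it widens to the full circle whenever the rectangle
  spans the origin.
* delta-OR cells are proportions centered per participant; their
  variance depends on per-cell trial counts, which the ANOVA's
  homoscedasticity assumption ignores.  The type-I calibration shows
  the phase test holds its nominal level under the generator's null,
  which is evidence for the synthetic conditions, not for arbitrary
  real data.
* The conceptual thalamic mechanism itself (relay-cell burst cycling)
  is outside the package's scope: the generator implements the
  phenomenological gating model, not a biophysical simulation.
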