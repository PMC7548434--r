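# alphashutter

Does the phase of the posterior EEG alpha rhythm gate whether a faint
flash is seen?  `alphashutter` implements a complete, tested analysis
of that question for researchers in visual/cognitive
electrophysiology.  Its distinguishing feature is *conduction-delay
referencing*: alpha phase and amplitude are read not at stimulus onset
but at each observer's individual retina-to-V1 conduction delay
(`t2`), estimated from the peak latency of the C1 visual-evoked
potential.  Under the "neuronic shutter" account of alpha -- cycling
excitability of the thalamo-cortical visual relay -- that is the moment
at which cortical phase reflects the excitability state that decided
the stimulus's fate.

## What the package computes

For each participant, with flash events and multichannel EEG:

* zero-phase Butterworth band-pass (0.01--50 Hz, -6 dB at the edges),
  averaged-mastoid reference, vEOG derivation, 512-Hz analysis rate;
* `t2` from the upper-minus-lower checkerboard VEP difference wave
  (blink-screened, baseline-corrected; most negative peak in
  0--110 ms);
* 10-Hz complex Morlet phase (90° = peak) and peak-to-peak amplitude
  (`2 * sqrt(power)`) of the pooled left/right occipital signals,
  read per trial at `t0 + t2`, with trials rejected when the
  hemispheres' phases disagree by more than 90°;
* observation rates per amplitude (median split) x phase (90° bins at
  0/90/180/270°) cell, expressed as ΔOR = cell OR − overall OR
  (percentage points);
* 360-point rotating-bin ΔOR profiles, their center-of-mass
  *preferred phase* φ_pref = arg Σ_c ΔOR(c)·e^(ic), the *pessimal
  phase* φ_pref − 180°, the *preferred phase effect*
  PPE = ΔOR(φ_pref) − ΔOR(φ_pessimal), and estimated angular 95% CIs;
* the statistical battery: 2 x 4 within-subject rmANOVA with Mauchly
  sphericity tests, partial η², observed power, Tukey HSD between
  phase bins within amplitude levels, and Bonferroni-corrected
  one-sample t tests of ΔOR against zero.

A first-class synthetic-data module (`gen_shutter_recording()`,
`gen_vep_recording()`, `run_staircase()`) embeds a known gating effect
`p(observed) = base + depth_i · cos(φ_i − φ_true)` in realistic alpha
(drifting phase, log-normal envelope, 1/f noise), so the whole chain is
validated by parameter recovery.

## Worked example

Simulate a 5-participant cohort with the shutter effect embedded at a
preferred phase of 270° (the alpha trough) and run the full pipeline:

```r
library(alphashutter)

cfg <- shutter_config(n_trials = 120,
                      inter_stimulus_interval_range = c(2, 3))
cohort <- simulate_cohort(n_participants = 5, config = cfg, seed = 42)
pipe <- run_pipeline(cohort)
pipe
#> <shutter_pipeline> 5 participants (0 excluded)
#> Two-way within-subjects ANOVA (n = 5)
#>   amplitude            F(1,4) = 0.008, p = 0.9316, eta_p^2 = 0.0021, power = 0.051
#>   phase                F(3,12) = 4.868, p = 0.0193, eta_p^2 = 0.5489, power = 0.784
#>   amplitude x phase    F(3,12) = 0.223, p = 0.8789, eta_p^2 = 0.0527, power = 0.081
#>   Mauchly phase        chi2(5) = 1.323, p = 0.9325
#>   Mauchly amplitude x phase chi2(5) = 3.275, p = 0.6576
#>   high-amplitude preferred phase 270.85 deg, PPE 29.28%, 95% CI [196.96, 343.72] deg
#>   low-amplitude preferred phase 263.98 deg, PPE 29.07%
```

The embedded 270° preferred phase is recovered (270.85° in the
high-amplitude condition), the phase effect is significant even at this
small cohort size, and the PPE says observation rates are ~29
percentage points higher at the preferred than at the pessimal phase.
(At 5 participants the angular CI is wide and the low-amplitude CI
degenerates to the full circle -- the pipeline warns when that
happens.)  `write_pipeline_results(pipe, "out/")` serializes the ΔOR
table, ANOVA, post hoc tables and preferred-phase JSON.

The analysis wavelet's characterization:

```r
k <- morlet_wavelet(10, 8/3, 512)
measure_fwhm_time(k)          # 101.5625 ms
measure_fwhm_freq(k)$fwhm_hz  # 8.8699 Hz
```

i.e. ~100 ms of temporal smoothing and an effective band-pass of
roughly 5.6--14.4 Hz, the alpha band.

Psychophysical calibration with the 1-up/1-down staircase:

```r
obs <- simulated_observer(threshold = 117, slope = 0.3)
tr <- run_staircase(obs, start_intensity = 150, step = 4,
                    n_trials = 40, seed = 7)
tr
#> <staircase_trace> 40 trials, 20 reversals, threshold 117.70
```

The threshold (mean intensity of all trials after the third reversal)
lands next to the observer's true 50% point of 117.

## Documentation

The methods vignette (`vignettes/alphashutter-methods.Rmd`) describes
the model, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the numerical
conventions (epoch indexing, wavelet truncation and FWHM measurement,
tie-breaks, degenerate inputs, error terms).
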