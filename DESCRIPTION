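Package: alphashutter
Title: Conduction-Delay-Referenced Analysis of Alpha-Phase Effects on
    Visual Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of how the phase and amplitude of the
    posterior EEG alpha rhythm, read out at each observer's individual
    retina-to-V1 conduction delay, predict detection of near-threshold
    visual flashes.  Provides a synthetic EEG generator with an embedded
    phase-dependent "shutter" effect, zero-phase Butterworth
    preprocessing, C1 visual-evoked-potential latency estimation,
    complex Morlet phase/amplitude extraction, hemispheric-asynchrony
    trial rejection, phase-binned observation-rate statistics with
    rotating-bin preferred-phase profiles, and the accompanying
    repeated-measures statistical battery (two-way within-subject
    ANOVA, Mauchly sphericity, partial eta squared, observed power,
    Tukey HSD, Bonferroni one-sample t tests), plus adaptive-staircase
    threshold estimation for psychophysical calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
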