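Package: actirhythm
Title: Circadian Rhythm Analysis of Home-Cage Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of spontaneous locomotor activity recorded as RFID visit
    event streams in the home cage: binning onto a light-schedule-aware
    zeitgeber-time axis, single-component cosinor rhythmometry (mesor,
    amplitude, acrophase), chi-square periodogram period estimation on a 20-25 h
    grid, detrended fluctuation analysis of activity fluctuations, and detection
    of the daily active phase (onset, offset, duration) from Gaussian-smoothed
    above-mean activity. Includes a synthetic actigraphy generator with
    phenotype presets (circadian period, amplitude, photic gating, long-range
    correlated noise via fractional Gaussian noise) under configurable
    light-dark schedules, so every stage of the pipeline can be validated
    against known ground truth, plus simulation of sparse clock-gene expression
    time courses for cosinor analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
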