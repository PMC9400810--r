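Package: cardiocortex
Title: Heart-Brain Coupling Analysis for Simultaneous EEG and ECG
Version: 0.1.0
Authors@R:
    person("cardiocortex", "developers", email = "dev@cardiocortex.invalid",
           role = c("aut", "cre"))
Description: Tested, reusable pipeline for resting-state heart-brain coupling
    analysis of simultaneous multichannel EEG and single-lead ECG: QRS/R-peak
    detection (Pan-Tompkins-style chain) and normal-to-normal interval
    derivation; time- and frequency-domain heart rate variability metrics
    (SDNN, RMSSD, Poincare SD1, absolute HF power); Welch band-power mapping
    of a 19-channel 10/20 montage onto lobe/hemisphere regions of interest;
    heartbeat-evoked potential averaging with channel-wise group statistics;
    and a cross-modal battery of Spearman correlograms, Bonferroni-corrected
    one-way ANOVA and exhaustive best-subset least-squares regression with
    adjusted-R-squared selection. Ships a deterministic synthetic-cohort
    generator with controllable heart-brain coupling so every stage is
    testable end to end without clinical data, plus minimal European Data
    Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
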