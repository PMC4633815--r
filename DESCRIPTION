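Package: erpcue
Title: Simulation and Analysis of Cross-Modal Cueing Infant ERP Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse event-related potential (ERP)
    experiments in which auditory cues predict the category of a masked
    visual target presented to infants. Provides a probabilistic trial-design
    generator (no-cue / valid / invalid cue conditions with per-block duration
    balancing), a synthetic 128-channel EEG epoch simulator with
    condition-dependent ERP component kernels, 1/f background noise and
    injected artifacts, an infant-specific preprocessing chain (average
    reference, band-pass filtering, bad-channel detection and interpolation,
    trial rejection, high-amplitude temporal smoothing, baseline correction),
    occipito-temporal ROI component-amplitude extraction, and an inference
    layer with repeated-measures ANOVA, paired post-hoc tests and a temporal
    cluster-based permutation test with exact small-n enumeration and
    Monte-Carlo family-wise error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
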