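Package: gliasleep
Title: Sleep Scoring, Microglia Calcium and Neuromodulator Sensor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible signal-analysis pipeline for studies of
    microglia-brain-state interactions: EEG/EMG sleep scoring into
    wake/NREM/REM hypnograms with episode segmentation and state metrics,
    sliding-percentile delta-F/F baseline estimation and threshold-based
    calcium transient detection for two-photon ROI traces, state- and
    transition-aligned trace summaries, window-contrast quantification of
    GRAB-type fluorescent sensor pharmacology sessions, anisotropic 3D
    nearest-distance analysis of axonal boutons to microglia masks, and
    group-level statistical wrappers. Every pipeline stage can be exercised
    on seeded synthetic data with embedded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
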