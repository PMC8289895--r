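Package: coordcca
Title: Coordination-Complexity Features and CCA Fusion for Multimodal
    Cognitive-Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts coordination-complexity features (eigenspectra of
    channel-delay correlation matrices) from multichannel physiological time
    series - smooth-pursuit gaze coordinates, speech formant tracks, and
    resting-state fMRI region-of-interest signals - and fuses them through a
    two-level PCA and canonical correlation analysis (CCA) model to predict a
    latent cognitive factor derived from ImPACT composite scores. Includes
    blink-aware gaze preprocessing, nested leave-one-subject-out
    cross-validation with per-feature-set dimensionality selection,
    within-subject change analysis with range-restriction adjustment, and a
    synthetic-cohort generator that plants a latent factor jointly modulating
    signal complexity and composite scores so every stage is testable without
    access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
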