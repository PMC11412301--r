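Package: torquematch
Title: Isometric Torque-Matching Psychophysics and Muscle-Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-phase isometric elbow torque-matching
    experiments performed under concurrent shoulder abduction loads. Provides a
    synthetic cohort generator emulating the trial protocol (reference phase with
    visual feedback, feedback-free match phase, multichannel surface EMG),
    EMG envelope preprocessing (zero-phase low-pass and 60 Hz notch filtering,
    rectification, RMS smoothing, MVC normalization), per-trial torque features
    (force-steadiness coefficient of variation, flexor-extensor coactivation,
    stabilization time), perceptual outcomes (constant and variable matching
    error), muscle-synergy extraction by nonnegative matrix factorization with
    VAF-based model selection and a random-synergy similarity threshold, and
    Spearman rank correlations with exact small-sample p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
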