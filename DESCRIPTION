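Package: uhdfinger
Title: Ultra-High-Density EEG Finger-Movement Decoding Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decoding single-finger extension movements
    from ultra-high-density (uHD) scalp EEG recorded with electrode grids at
    8.6 mm pitch over the sensorimotor cortex. Provides hemispherical montage
    construction with neighbor graphs and reduced-density electrode subsets,
    preprocessing (polyphase resampling, Butterworth notch cascade,
    statistical bad-channel and bad-run rejection, common average
    referencing), mu/beta log band-power features with drift compensation and
    epoching, event-related desynchronization/synchronization (ERD/S) maps
    with scalp heatmap interpolation and focal electrode selection,
    time-resolved pairwise linear-SVM classification with repeated stratified
    cross-validation, permutation-based empirical p-values and
    Benjamini-Hochberg correction, and neighboring-electrode redundancy
    analysis. A synthetic uHD-EEG generator with finger-specific oscillatory
    sources makes the full pipeline testable end to end without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
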