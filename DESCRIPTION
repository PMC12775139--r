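Package: frustbci
Title: Frustration-Aware Adaptive Motor-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating frustration-aware adaptive
    motor-imagery (MI) brain-computer interfaces from multichannel EEG.
    Implements filter-bank common spatial pattern (FBCSP) feature extraction
    with mutual-information feature selection, passive-BCI decoding of graded
    frustration (low/medium/high) induced by probabilistic task feedback,
    state-specific MI classifier banks, and two strategies for combining the
    two decoders: hard switching on the most probable state and probabilistic
    (soft) fusion of all state-specific MI outputs, benchmarked against
    state-agnostic baselines. Includes EDF and BrainVision readers, a
    preprocessing and sliding-window segmentation pipeline with a trial-level
    leakage guard for cross-validation, band-wise spectral statistics, cohort
    aggregation utilities, and a synthetic EEG cohort generator that emulates
    lateralized sensorimotor event-related desynchronization and
    frustration-dependent beta/gamma power shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
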