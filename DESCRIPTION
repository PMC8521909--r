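Package: jaescore
Title: Joint Acoustic Emission Analysis and Knee Health Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for joint acoustic emissions (JAEs) recorded
    from the knee with skin-contact accelerometers during flexion/extension
    exercise. Provides a seeded synthetic-cohort generator (noise-like healthy
    signals versus click-laden arthritic signals), FIR band-pass filtering,
    IMU-based movement-cycle segmentation, short-time audio feature extraction
    (zero-crossing rate, energy, entropy, spectral centroid/spread/roll-off/
    flux/entropy/density) summarized per cycle, leave-one-subject-out logistic
    regression with fold-local standardization, a per-subject joint health
    score with threshold classification and ROC metrics, coefficient-magnitude
    feature importance with a feature-by-cycle accuracy grid, and paired
    longitudinal score tracking with a one-tailed t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
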