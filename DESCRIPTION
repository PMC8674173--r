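Package: movelem
Title: Movement-Element Decomposition of Wrist Kinematics for Ataxia Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decomposes wrist-worn accelerometer recordings of repeated
    reaching (the finger-to-nose test) into one-dimensional movement
    elements bounded by velocity zero-crossings, engineers per-participant
    kinematic features (size, speed, duration, speed-distance power law,
    consecutive-element transitions, and velocity-profile morphology), and
    estimates ataxia severity and phenotype with leave-one-subject-out
    Gaussian-process models. Includes a synthetic finger-to-nose cohort
    generator so the full pipeline is testable without clinical data, plus
    the evaluation statistics used for digital-biomarker validation (RMSE,
    bootstrap AUC, ICC(3,1), Welch ANOVA, Games-Howell).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
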