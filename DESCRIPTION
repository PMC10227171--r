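Package: gazepred
Title: Simulation and Analysis of Pursuit, Predictive Saccades and
    Time-to-Contact Prediction Under Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prediction-motion ('eye-cricket') experiments in which
    observers pursue a moving target, respond to a speed perturbation with a
    predictive saccade to a fixation cross (or a button press), monitor the
    occluded target peripherally, and judge its time to contact (TTC).
    Provides an analytic stimulus model (piecewise constant-velocity target
    with occlusion), quasi-randomized factorial designs, a seeded synthetic
    oculomotor data generator with ground-truth labels, velocity-based
    saccade detection with a fixed 22 deg/s threshold and zero-phase 60 Hz
    low-pass filtering, trial validity/correctness scoring with TTC
    prediction errors, and within-subject statistics (repeated-measures
    ANOVA with Greenhouse-Geisser correction, Holm-adjusted contrasts,
    partial eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
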