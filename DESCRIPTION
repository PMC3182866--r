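Package: objadapt
Title: State-Space Models of Trial-by-Trial Adaptation to Object Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, fits and compares trial-by-trial state-space models of
    motor adaptation to the dynamics of a hand-held rotated object. Implements
    single-rate, dual-rate and multiple-context single-rate learners with a
    Gaussian orientation-tuned context-selection vector and a
    compliance-dependent error, rigid-body load computation for the rotated
    object, deterministic builders for the experiment trial schedules,
    bounded least-squares model fitting with BIC model selection and
    subject-resampling bootstrap confidence intervals, synthetic cohort
    generation for parameter-recovery studies, and the derived analyses
    (generalization curves, mass slopes, orientation-change binning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
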