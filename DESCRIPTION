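Package: keydyn
Title: Keystroke Dynamics Screening for Depressive Tendency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects depressive tendency from in-the-wild touchscreen typing
    patterns. Extracts keystroke dynamics variables (hold time, flight time,
    inter-key speed, press-flight rate) from raw typing-session event streams
    with conditional timing filters, assembles 20-dimensional session feature
    vectors, and classifies subjects with a leave-one-subject-out pipeline
    using nested 5-fold feature selection (ANOVA F select-k-best) and grid
    search, averaging session probabilities per subject. Includes bootstrap
    ROC analysis with Youden operating points, group-wise Mann-Whitney
    feature tests, PHQ-9 scoring with 5/10 cutoffs, prediction-probability
    convergence and daily-trajectory analysis, and a seeded synthetic
    typing-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
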