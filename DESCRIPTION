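Package: surgrsd
Title: Remaining Surgery Duration Prediction from Surgical Workflow Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intra-operative remaining surgery duration (RSD) prediction for
    endoscopic pituitary surgery from per-second workflow annotations and
    frame features. Implements the statistical estimators (naive mean,
    step-inferred, and Levenshtein sequence-matching k-nearest-neighbour,
    optionally instrument-augmented), a multi-task two-layer LSTM that
    jointly predicts the current surgical step and the normalized RSD with
    prior-step-context input features, a calibrated surgical-workflow
    simulator (core/optional steps, repeatable haemostasis, long-tailed
    durations), and an evaluation harness with per-video mean absolute
    error over full/last-20/last-10-minute windows, macro-F1 step scores
    and paired Wilcoxon signed-rank comparisons.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
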