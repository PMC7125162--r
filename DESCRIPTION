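Package: motorstate
Title: Motor-State Detection for Parkinson's Disease from a Wrist-Worn Accelerometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects OFF, ON and dyskinetic motor states of people with
    Parkinson's disease from tri-axial wrist accelerometry. Implements the
    full analysis pipeline: zero-phase Butterworth band-pass filtering and
    resampling of raw sensor streams, one-minute windowing with low-variance
    rejection, rotational and sliding-window data augmentation with
    float-label interpolation, a convolutional ensemble classifier trained on
    random patient subsets, expected-value aggregation of softmax outputs
    (expCNN) with LOESS-smoothed day curves, and leave-one-subject-out
    clinimetric evaluation (balanced accuracy, Cohen's kappa, one-vs-all
    sensitivity and specificity, windowed Pearson correlations, ICC(2,1)
    rater reliability). Ships a synthetic cohort simulator so that every
    stage is testable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    generics,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    randomForest,
    class,
    nnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
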