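Package: attnmvpa
Title: Time-Resolved EEG Decoding of Feature-Based Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of feature-based attention from EEG. Generates counterbalanced
    rapid-serial designs of overlaid orientation stimuli, simulates continuous
    multichannel EEG with linearly superposed orientation-selective evoked
    responses and a configurable attention-dependent gain, preprocesses and
    epochs the recordings, decodes cued and uncued orientations per timepoint
    with regularised linear discriminant analysis under leave-one-sequence-out
    cross-validation, and performs group-level inference with interval-null
    Cauchy-prior Bayes factors, bootstrap confidence intervals and
    onset-latency detection.
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
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
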