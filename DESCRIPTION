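Package: cascadenet
Title: Confidence-Gated Two-Stream Convolutional Cascades with Feature Reuse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic early-exit inference for image classification: a small
    convolutional stream scores every sample at low resolution, a confidence
    threshold routes hard samples to a larger stream at higher resolution,
    and feature reuse modules inject the small stream's per-stage features
    into the large stream through bilinear upsampling, 1x1 channel
    alignment and pointwise addition. Includes the two-step training
    protocol (independent stream training, then fine-tuning of the large
    stream with the reuse modules), analytic multiply-accumulate cost
    accounting, one-vs-rest ROC/AUC evaluation, and a synthetic
    small-lesion image generator with controlled easy/hard difficulty
    strata so the whole mechanism is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    png,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    EBImage
Config/testthat/edition: 3
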