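Package: germdetr
Title: Detection-Transformer Phenotyping of Seed Germination in Soil Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting germinating seeds in top-down images of
    soil-filled culture dishes and for turning the detections into
    germination-vigor statistics. Implements a lightweight real-time
    detection transformer with a re-parameterizable backbone (ADown
    downsampling, GELAN split-and-aggregate stages, online convolutional
    re-parameterization), a set-prediction training objective that mixes
    generalized IoU with the normalized Gaussian Wasserstein distance for
    tiny radicle targets, COCO-style detection evaluation, a deterministic
    synthetic soil-scene generator with ground-truth annotations, and
    germination-rate / germination-index time-series reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    xml2,
    png,
    EBImage,
    stats,
    utils,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
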