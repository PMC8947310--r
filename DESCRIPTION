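Package: tonguecaps
Title: Capsule Networks for Tongue Color Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying tongue body color (light
    red, red, deep red, light white, cyan) from segmented tongue photographs
    with a capsule network. Provides deterministic preprocessing (letterbox
    resize to a square, HSV conversion, power-law brightness adjustment), a
    class-balancing augmentation engine, a seeded synthetic tongue-image
    generator for testing without clinical data, the capsule primitives
    (squash, prediction transform, dynamic routing by agreement, margin loss),
    the TongueCaps residual-convolution capsule architecture with shape
    tracing and parameter/FLOP accounting, and training/evaluation utilities
    (stratified splits, grid search with k-fold cross-validation, one-vs-rest
    macro metrics) with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
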