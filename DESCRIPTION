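Package: ghostherd
Title: Lightweight Ghost-Attention Networks for Cattle Coat-Pattern Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, audits and trains a lightweight residual convolutional
    network for individual Holstein cow identification from side-view
    coat-pattern images. The trunk is a reduced three-stage residual network
    with a dilated-convolution stem, GhostBottleneck blocks that synthesize
    part of each feature map with cheap depthwise operations, and a
    channel-plus-spatial attention block after every stage. The package
    includes an exact accounting engine for trainable parameters,
    multiply-accumulate operations and FP32 model size; a deterministic
    configuration search that reverse-engineers trunk widths against printed
    parameter ledgers; the full training recipe (stratified 70/20/10 split,
    rotation tripling, Xavier initialization, momentum SGD with step decay);
    and a synthetic coat-pattern herd generator so the whole pipeline is
    testable without proprietary farm imagery. All network computation,
    including backpropagation, is implemented in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
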