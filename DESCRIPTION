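Package: nodulemsa
Title: Multi-Scale Attention Networks for Pulmonary Nodule Detection in 3D CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pulmonary nodule detection system for thoracic CT
    volumes built on 3D multi-scale attention (MSA) blocks: a Res2Net-style
    hierarchical channel split with pre-activated convolutions and a
    four-branch convolutional quadruplet attention module. Provides MetaImage
    volume input/output, Hounsfield-unit preprocessing and lung parenchyma
    segmentation, an anchor-based candidate detector with a U-Net-like
    encoder-decoder backbone, a false-positive-reduction classifier,
    sliding-window inference with 3D non-maximum suppression, FROC/CPM
    evaluation with bootstrap confidence bands, and a seeded synthetic CT
    phantom generator so the full pipeline is testable without external data.
    The neural-network layers and their gradients are implemented in R and
    C++ within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
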