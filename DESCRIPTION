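Package: zonereg
Title: Enhancer Grammar, Reporter Activity and Spatial Zonation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting enhancer-driven liver zonation at desk scale:
    a motif-grammar simulator with known ground truth, region and sequence
    plumbing (iterative consensus-peak merging, window augmentation, one-hot
    encoding), a convolutional sequence classifier with PWM filter
    initialization and transfer learning, sequence interpretation (attribution
    maps, in-silico saturation mutagenesis, information-content motif trimming,
    instance scanning and gain/loss-of-function variant design), massively
    parallel reporter assay (MPRA) processing with a shuffled-control Gaussian
    null, in-silico transcription-factor perturbation of an enhancer-driven
    gene regulatory network, and pseudotime-to-spatial mapping onto a virtual
    liver lobule with spline tests for zonated features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
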