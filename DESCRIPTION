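Package: vascam
Title: Vessel Segmentation and Angiogenesis Quantification for the Chick
    Chorioallantoic Membrane Assay
Version: 0.1.0
Authors@R: person("vascam", "developers", email = "vascam@example.org",
    role = c("aut", "cre"))
Description: Quantifies tumor-induced angiogenesis in microscopy images of
    the in ovo chick chorioallantoic membrane (CAM). Provides a compact
    trainable encoder-decoder (U-net style) vessel segmenter with tiled
    inference, skeleton-based vascular morphometry (total vessel area,
    total vessel length, mean vessel thickness, branching points), a laser
    speckle contrast imaging (LSCI) style perfusion summary with stable
    frame selection and perfusion-unit band filtering, one-way ANOVA with
    Tukey HSD group statistics computable from raw data or from printed
    summary statistics, and a synthetic CAM image generator with analytic
    ground truth so the whole pipeline is testable without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
SystemRequirements: zlib
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
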