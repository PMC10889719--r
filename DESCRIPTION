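Package: trabekit
Title: Three-Dimensional Histological Reconstruction and Trabecular
    Micromorphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to rebuild a three-dimensional tissue volume from stained
    serial sections and to validate the reconstruction against micro-computed
    tomography (microCT) of the same specimen.  Provides slide pre-processing
    (tissue detection, coarse rotation, downsampling), keypoint-based stack
    pre-alignment with a sequential cross-entropy affine optimizer,
    cross-modal slice matching against an in-silico sliced microCT volume,
    tile-based three-class tissue segmentation with a small convolutional
    encoder-decoder network, an open implementation of standard 3D trabecular
    micromorphometric parameters (BV/TV, BS/TV, Tb.Th, Tb.Sp, Tb.Pf, SMI, DA,
    fractal dimension, Euler number and friends), and the method-comparison
    statistics (Spearman correlation, Bland-Altman analysis, mountain plots)
    used to assess agreement between the two modalities.  A synthetic phantom
    generator supplies trabecular volumes, simulated microCT renderings and
    jittered histology stacks with full ground truth, so the entire pipeline
    is testable without external data.
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
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    tiff,
    png,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
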