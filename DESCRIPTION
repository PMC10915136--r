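Package: embryoqp
Title: Label-Free Embryo Health Profiling from Quantitative Phase Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing preimplantation embryo health from
    quantitative phase z-stacks. Implements four-frame phase-shifting
    reconstruction with spectral gradient integration, two-stage 3D nucleus
    instance segmentation (per-slice thresholding and watershed followed by
    z-trajectory linking with stacked-nucleus splitting and morphological
    filters), per-nucleus dry-mass and shape feature extraction,
    trophectoderm/inner-cell-mass compartment assignment, a scattering
    amplitude spectrum half-power bandwidth biomarker, a feature-based
    neural-network health grader with max-voting aggregation, image
    similarity metrics (PSNR, MS-SSIM, Pearson) and a normality-gated group
    comparison pipeline. A synthetic embryo generator with exact ground
    truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    nortest,
    car,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
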