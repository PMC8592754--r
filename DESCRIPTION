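Package: ateopipe
Title: Mammogram Mass Analysis with an Advanced Thermal Exchange Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for candidate-mass detection in
    mammograms together with the Thermal Exchange Optimization (TEO)
    metaheuristic and its Advanced variant (ATEO). The pipeline chains
    lookup-table contrast stretching, Wang-Mendel fuzzy-rule denoising,
    XYZ colour-space normalization with Otsu thresholding, binary
    morphology, wavelet-subband GLCM texture features, and a small
    convolutional classifier whose weights are trained by ATEO in place of
    backpropagation. A benchmark-function harness evaluates the optimizer
    over repeated independent runs, and a synthetic phantom generator
    provides reproducible MIAS-like test images with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
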