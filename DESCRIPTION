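Package: swaunet
Title: Longitudinal Forecasting of Geographic Atrophy Lesion Growth from
    Fundus Autofluorescence Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements SWAU-Net, a regularized hybrid convolutional and
    attention-based encoder-decoder for forecasting geographic-atrophy (GA)
    lesion masks and growth masks from longitudinal fundus-autofluorescence
    (FAF) image sequences. Provides a synthetic anisotropic lesion-growth
    simulator for pretraining, the hybrid Dice/BCE/L1 loss and two-stage
    training protocol, Dice-based evaluation with five-fold cross-validation
    aggregation, the Nadeau-Bengio corrected resampled t-test for model
    comparison, and the full ablation suite on the shared backbone. The
    network, its reverse-mode automatic differentiation engine and the Adam
    optimizer are implemented in R with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
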