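Package: mfnet
Title: Frequency-Space Amplitude Mixing and Meta-Learning for
    Domain-Generalizable Lesion Segmentation
Version: 0.1.0
Authors@R: person("mfnet", "maintainers", email = "mfnet@example.org",
    role = c("aut", "cre"))
Description: Training toolkit for single-source domain generalization in
    binary medical-image segmentation. Decomposes 2D grayscale slices into
    Fourier amplitude and phase spectra, interpolates amplitude spectra
    across co-registered modalities of the same case to synthesize
    style-shifted training samples, and trains a U-Net with a two-task
    meta-learning objective (Dice loss on original data, Dice loss on mixed
    data at inner-loop-adapted parameters) optimized by SGD with a
    polynomial learning-rate schedule. Ships a multi-modal two-domain
    synthetic head-slice phantom generator so the whole pipeline is testable
    without patient data, plus Dice/MIoU evaluation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
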