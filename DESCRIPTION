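Package: oostage
Title: Two-Stage Deep-Network Staging of Human Oocyte Meiotic Maturity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic staging of single human oocytes into the
    meiotic maturity classes MI, MII and PI from grayscale microscopy
    images. The pipeline first extracts the germinal vesicle (GV) and
    first polar body (FPB) regions with a semantic segmentation network,
    then classifies the oocyte from the extracted region channels with a
    compact fire-block convolutional network whose per-layer filter
    counts are refined by a genetic algorithm under an accuracy-plus-
    parameter-budget objective. Includes a synthetic oocyte phantom
    generator with class-conditional ground-truth masks, stratified
    repeated random subsampling (SRRS) validation, class-balanced batch
    sampling, analytic FLOPs accounting, detection-ratio model selection
    and the full per-class quality-coefficient suite. The convolutional
    engine (forward/backward convolution, pooling, upsampling, Adam) is
    implemented with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
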