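Package: pssahcs
Title: Prediction-Based Spatial-Spectral Adaptive Hyperspectral Compressive Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compressor and reconstructor for hyperspectral image cubes based on
    block compressive sensing with spatial-spectral adaptation. The spatial block
    size is chosen from the image's spatial autocorrelation, bands are grouped by
    k-means clustering on interband Euclidean distance, each group's least-noisy
    band is selected as the key band by a local-means/local-standard-deviations
    (LMLSD) criterion, and non-key bands are coded as residuals of a closed-loop
    affine prediction from the reconstructed key band. Sampling uses a seeded
    Gaussian measurement matrix with an orthonormal 2-D DCT sparse basis and
    stagewise orthogonal matching pursuit (StOMP) recovery. Includes ENVI/BSQ
    input-output, a self-contained compressed-package container, the standard
    evaluation metrics (PSNR, spatial and spectral correlation), and a synthetic
    cube generator emulating visible/near-infrared plant imagery with noisy
    atmospheric-absorption bands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
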