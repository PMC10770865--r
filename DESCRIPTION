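Package: phasorFLIM
Title: Phasor Denoising and Segmentation for Frequency-Domain FLIM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for frequency-domain fluorescence lifetime imaging
    microscopy (FLIM) phasor analysis. Simulates four-phase homodyne FLIM
    measurements with mixed Poisson-Gaussian detector noise, extracts
    real/imaginary (G/S) measurement planes, per-pixel lifetimes and phasor
    coordinates, denoises the phasor planes with iterative median filtering
    or a small residual convolutional neural network (supervised or
    Noise2Noise training), segments fluorophores by K-means clustering of
    the phasor cloud, and evaluates results with PSNR/SSIM and composite
    HSV lifetime renders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, grDevices, utils, tiff, png, yaml, minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, jsonlite, optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'phasorFLIM-package.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'simulate.R'
    'phasor.R'
    'denoise.R'
    'segment.R'
    'metrics.R'
    'render.R'
    'pipeline.R'
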