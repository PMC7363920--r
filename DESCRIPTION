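Package: pedorient
Title: Pedestrian Shoulder-Line Orientation from Overhead Depth Imagelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the shoulder-line orientation of walking pedestrians from
    small overhead depth images ("imagelets") using a compact convolutional
    network trained on velocity-direction weak labels, with orientations treated
    as elements of the real projective line. Provides exact projective-line
    circular statistics (two-hot encoding, circular-average decoding), a
    synthetic two-ellipse imagelet generator with known ground truth, O(2)
    group-averaged (rotation/reflection equivariant) prediction, the
    bias/ARMSE evaluation protocol with learning-curve drivers, and an
    Ornstein-Uhlenbeck stochastic-delay model coupling velocity direction to
    body orientation (simulation, delay estimation by windowed
    cross-correlation, amplitude recovery, and spectral comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    readr,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
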