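Package: filasense
Title: Simulated Laser-Filament Particle Emission Imaging and CNN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and analysis of single-particle optical
    emission events in a femtosecond laser filament. Generates synthetic
    camera frames of filament-particle interaction for four particle classes
    (blank, chalk, pollen, salt) from parametric plasma emission spectra,
    trains a convolutional neural network to classify them, and runs the
    downstream analyses: Grad-CAM saliency with red-green chromaticity
    cluster statistics (silhouette, Mahalanobis), dark-field particle
    morphometry, a phenomenological intensity-clamping spectral model with
    continuum-broadening onset detection, and air-sampler concentration
    arithmetic. The network layers (convolution, batch normalisation, max
    pooling, Adam) are implemented natively with fast single-precision
    linear algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    pracma,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
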