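Package: mbvelo
Title: Localization-Free Super-Resolution Microbubble Velocimetry
Version: 0.1.0
Authors@R: person("MB", "Velo Developers", email = "mbvelo@example.org",
    role = c("aut", "cre"))
Description: Simulation, learning and evaluation toolkit for super-resolution
    ultrasound velocimetry of microvascular blood flow without explicit
    microbubble localization. Converts vascular template images into directed,
    velocity-annotated vessel graphs; simulates microbubble populations
    advecting through the graph under a laminar flow profile with
    area-weighted branching; renders diffraction-limited contrast ultrasound
    frame sequences by point-spread-function convolution with Rayleigh noise;
    trains a convolutional LSTM-UNet that regresses dense velocity
    magnitude/angle maps directly from frame sequences; and provides a
    conventional localize-and-track baseline plus evaluation metrics (velocity
    RMSE, vessel FWHM, Fourier ring correlation resolution, and
    mass-conservation flow-channel references).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml,
    rhdf5,
    withr
Config/testthat/edition: 3
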