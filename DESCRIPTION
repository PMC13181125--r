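Package: navcode
Title: Position and Visual Coding Analysis for Cortical Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for head-fixed two-photon calcium imaging
    experiments on a cued circular treadmill, with a matching synthetic-session
    generator. Implements neuropil correction, min/max baseline estimation,
    non-negative AR(1) spike deconvolution with a fixed exponential kernel,
    running-epoch and lap segmentation, occupancy-normalized position tuning
    maps with a circular-shift shuffle test, spatial information and
    trial-to-trial reliability, Bayesian population decoding of position with
    odd/even and k-fold cross-validation, drifting-grating visual tuning
    metrics (reliability index, SF/TF preference, OSI/DSI), Fourier phase
    retinotopy for widefield movies, and retrograde-tracing input
    quantification over a brain-region hierarchy (input fractions, volume
    densities, log2 bias index, dorsoventral profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
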