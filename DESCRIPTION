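Package: dvn
Title: Cross-Hair Convolutional Networks for 3-D Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting vascular structures in 3-D angiographic
    volumes with fully convolutional networks built from cross-hair
    (orthogonal-plane) filters. Provides the cross-hair convolution operator
    with a closed-form operation-count model, an extreme class-balancing
    cross-entropy loss with false-prediction-rate correction, a constrained
    synthetic vascular tree simulator (Murray's law and optimal bifurcation
    angles) with voxel rendering and vessel/centerline/bifurcation ground
    truth, a sub-sampling-free fully convolutional network with plain SGD
    training, segmentation metrics, hit-or-miss bifurcation scoring, NIfTI-1
    volume input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
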