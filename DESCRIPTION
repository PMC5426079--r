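Package: moorgb
Title: Multi-Objectively Optimized Graph-Based Segmentation of Ultrasound
    Tumor Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments tumors in B-mode ultrasound images with a
    minimum-spanning-tree region-merging segmenter whose two control
    parameters (k, alpha) are tuned per image by particle swarm
    optimization under a three-term objective combining between-class
    variance, arctan-damped within-class variance, and the average Sobel
    gradient along the candidate tumor boundary.  Includes the
    preprocessing chain (bilateral filter, histogram equalization,
    pyramid mean shift), morphological postprocessing, radial-error and
    volume-fraction evaluation metrics, and a deterministic synthetic
    speckle-phantom generator so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
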