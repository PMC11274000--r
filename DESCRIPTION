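Package: ovimorph
Title: Posture Classification and Body-Size Morphometry from Walking-Sheep Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures body-size traits of sheep walking through a capture
    channel from per-frame binary silhouette masks. Implements weighted-region
    key-frame selection, head-down/head-up/jump posture classification from a
    rectangle-angle statistic, anatomical landmark detection on the silhouette
    contour (maximal inscribed rectangle, convex hull and U-chord-length
    curvature), and pixel-to-centimeter conversion through calibrated cubic
    polynomial ratio models. Includes a parametric silhouette generator with
    known landmark ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
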