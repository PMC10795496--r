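Package: leafcomplete
Title: Point Cloud Completion and Leaf Area Estimation for Occluded Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-view 3D reconstruction of plants whose leaves are
    partially hidden by occlusion. Provides preprocessing filters and
    region-growing segmentation for RGB-D plant captures, an occlusion
    simulator that builds fixed-size completion training pairs
    (2,048-point incomplete clouds with 512-point missing ground truth),
    a multi-resolution point-fractal completion network trained with a
    multi-stage chamfer-distance loss, pose normalization and recovery,
    Delaunay 2.5D surface reconstruction with Laplacian smoothing for
    leaf-area measurement, and a parametric synthetic-leaf generator
    with analytic reference areas for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
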