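Package: bunchmetric
Title: Grape Bunch Phenotyping from Multi-View Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating phenotypic parameters of grape bunches from
    3D point clouds. Segments a bunch from raw single-view scans by cropping
    and curvature-seeded region growing, registers 12 turntable views into a
    complete 360-degree model with PCA coarse alignment, iterative closest
    point refinement, voxel-grid downsampling and moving-least-squares
    smoothing, extracts length/width/height in the bunch's own principal-axis
    frame, and estimates volume with five reconstruction methods: a bounding
    cylinder, the 3D convex hull, the 3D alpha-shape, voxel occupancy, and
    Poisson indicator-function surface reconstruction with signed-tetrahedron
    mesh volume. Includes a synthetic scanner that generates bunches of known
    geometry with a Monte-Carlo volume oracle, and evaluation utilities
    (error, RMSE, coefficients of determination) together with a packaged
    per-sample reference table for reproducing published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RANN,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
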