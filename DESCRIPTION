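Package: eatmotion
Title: Pericardial Adhesion Assessment from 4D Cardiac CT Motion Disparity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies relative motion between epicardial adipose tissue (EAT)
    and the pericardium across the cardiac cycle in four-dimensional cardiac CT,
    and classifies pericardial adhesion status from the shape of the motion
    disparity distribution. Nine cardiac phases are registered to the 50%
    reference phase with a diffeomorphic registration fallback (multi-resolution
    demons), the expert pericardial region is propagated to every phase, EAT is
    segmented by Hounsfield-unit thresholding, and EAT-pericardium displacement
    differences are normalized, restricted to a cylindrical region of interest
    around the left anterior descending artery centerline, and summarized by two
    histogram statistics: the peak ratio and the distribution width index. A
    synthetic beating-heart phantom with a tunable adhesion coupling parameter
    provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
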