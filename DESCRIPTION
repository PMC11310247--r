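Package: vesitrack
Title: Single-Particle Tracking and Quantification of Intracellular Vesicle Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying clathrin-coated vesicle dynamics in
    fluorescence microscopy. Simulates time-lapse movies and two-channel
    scenes with known ground truth, detects diffraction-limited spots by
    weighted least-squares Gaussian fitting, links detections into tracks
    by nearest-neighbour association with gap closing, and computes track
    statistics (mean square displacement, apparent diffusion constant,
    turning-angle asymmetry coefficient, track length). Also provides
    fixed-image metrics: rolling-ball background subtraction, Manders
    overlap colocalization with Costes automatic thresholds, thresholded
    mean intensity, and a cell-segmentation pipeline measuring vesicle
    distance-to-centroid and radial fraction-at-distance profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    tiff,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
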