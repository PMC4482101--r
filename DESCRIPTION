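Package: airwayseg
Title: Lung-Side-Specific Adaptive-Threshold Region Growing for Airway
    Segmentation in Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic segmentation of the trachea and bronchial tree
    from chest CT volumes in Hounsfield units. The trachea and the right and
    left bronchial trees are cropped and segmented independently by
    connected-threshold region growing with an iteratively adapted threshold;
    leakage into the lung parenchyma is controlled by geometric guards on the
    trachea label, by a growth-ratio test between consecutive thresholds, and
    by a per-lung voxel budget derived from the trachea voxel count via a
    reconstruction-kernel and slice-count lookup. Includes a synthetic
    bifurcating airway phantom generator with analytic ground truth,
    centerline-based branch metrics, NRRD/NIfTI volume input and output,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
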