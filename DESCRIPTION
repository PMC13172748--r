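Package: ccev
Title: Equivalent-Volume Concordance Coefficients for Radiotherapy Target
    Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares co-registered 3-D radiotherapy structure masks with
    equivalent-volume concordance coefficients (JC_EV, DSC_EV): Jaccard and
    Dice coefficients in which each non-overlapping sub-volume is weighted by
    a power of its physical distance to the other structure, discounting
    discrepancies that lie within the steep dose fall-off surrounding the
    target. Includes exact anisotropic Euclidean distance transforms and
    distance-banded segmentation of non-overlap regions, dose-volume-histogram
    (DVH) gradient analysis via equivalent-sphere radii to calibrate the
    distance penalty, digital sphere phantoms with closed-form oracles, and a
    small command-line interface. Masks are read from NIfTI or NRRD volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
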