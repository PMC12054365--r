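Package: sxcal
Title: Robust Error Calibration and Merging Statistics for Serial
    Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates the uncertainties of unmerged, scaled reflection
    intensities from serial crystallography experiments. Implements the
    Ev11 normalized-deviation calibration and a robust maximum-likelihood
    calibration based on normalized pairwise differences of
    symmetry-equivalent observations, with per-lattice error levels driven
    by the correlation of each lattice to a scaling reference and a
    half-normal or half-t likelihood. Includes inverse-variance weighted
    merging, CC1/2 and I/sigma statistics in resolution bins, Wilson
    second-moment and rankit diagnostics, and a model-conforming synthetic
    data generator so every stage can be validated without experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
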