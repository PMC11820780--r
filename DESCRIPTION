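Package: srmquant
Title: Quantification and Validation Workflow for Scheduled-SRM Targeted
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-acquisition computational workflow for dual-method
    (HILIC and reversed-phase) scheduled selected-reaction-monitoring (SRM)
    targeted metabolomics assays on triple-quadrupole instruments:
    transition-registry management and validation, scheduled-SRM dwell-time
    budgeting under a cycle-time budget with polarity switching, 1/x-weighted
    linear and quadratic calibration with LOD/LLOQ/ULOQ determination,
    carryover assessment, standard-addition apparent recovery and
    repeatability, instrument-drift correction, two-dilution
    recovery-corrected quantification with qualifier/quantifier ion-ratio
    confirmation and isomer deconvolution, and trueness reporting against
    certified reference values.  A synthetic peak-area generator with known
    ground truth stands in for the instrument in tests and simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
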