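Package: petseg
Title: Phantom-Based Evaluation of Automated PET Lesion Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Digital NEMA IQ and synthetic phantoms with exact ground truth,
    a simplified seeded image-domain PET emulator (resolution blur plus
    count-dependent Poisson noise), five SUV-threshold-family delineation
    algorithms (fixed 40/50 percent, regression-calibrated contrast
    thresholding, and background-adaptive 40/50 percent), recovery-coefficient
    harmonisation by a reconstruction-specific Gaussian filter fitted by RMSE
    minimisation, and a validation harness reporting similarity index,
    percentage volume error and coefficient of variation across an experiment
    grid of contrasts, reconstruction protocols, count levels and replicates.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
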