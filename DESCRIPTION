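Package: fermcal
Title: Model-Based Calibration of 2D Fluorescence Spectra for Online
    Fermentation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online monitoring of batch lactic-acid fermentations from
    two-dimensional fluorescence spectra without offline calibration data.
    Implements a closed-form batch growth/substrate/product process model,
    standard-normal-variate spectral preprocessing on a BioView-style
    excitation/emission channel grid, NIPALS partial least squares
    regression, and particle swarm optimization. The specific growth rate
    and the chemometric models are optimized jointly against simulated
    state variables (model-based calibration); the classical calibration
    against offline measurements is included for comparison, together with
    RMSE / percent-of-range validation reports and a synthetic-study
    generator emulating three batch cultivations with fluorophore-shaped
    spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
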