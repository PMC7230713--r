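Package: scalespec
Title: Hyperspectral Chemometrics for Fish Scaling-Rate Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and chemometric analysis of visible/near-infrared
    hyperspectral reflectance spectra of fish surfaces with mixed scale and
    skin coverage. Provides a synthetic scene and spectrum generator with
    white/dark reference frames, reflectance correction and region-of-interest
    extraction, the four standard spectral pretreatments (Savitzky-Golay
    smoothing, first derivative, multiplicative scatter correction, standard
    normal variate), characteristic-wavelength selection by the successive
    projections algorithm, regression-coefficient extrema and two-dimensional
    correlation spectroscopy auto-peaks, NIPALS partial least squares
    regression with cross-validated component selection, and the evaluation
    matrix (R2, RMSEC/RMSEP, RPD, grading) used to rank calibration models
    for scaling-rate prediction per fish body region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
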