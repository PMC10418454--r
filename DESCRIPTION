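Package: nirstew
Title: Dual-Band Near-Infrared Chemometrics for Meat Quality Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibration pipeline for dual-band (650-950 nm and 960-1660 nm)
    near-infrared reflectance spectra of processed meat products. Provides
    spectral ingestion and noise-band trimming, standard normal variate,
    detrend and Savitzky-Golay derivative preprocessing, NIPALS partial
    least squares regression with leave-one-out cross-validation for latent
    variable selection, wavelength selection by regression-coefficient
    extrema and by the random frog algorithm, RPD-based model evaluation,
    and a synthetic dual-band spectra generator with realistic trait
    distributions, scatter and baseline artifacts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
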