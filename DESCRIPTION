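Package: sptkit
Title: Single-Particle Tracking Mobility and Anomalous Diffusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-particle tracking data from
    fluorescence microscopy of membrane-protein puncta. Provides spot
    detection and nearest-neighbour linking with gap handling, fixed-cell
    calibration of the localization error, mobility classification by the
    scaled radius of gyration against a fixed-cell 95th-percentile threshold,
    time-averaged mean-squared displacement (TAMSD) computation with
    power-law fitting and noise- and heterogeneity-corrected ensemble
    anomalous exponent estimation, per-trajectory Rayleigh-mixture
    decomposition of step lengths with AIC model selection, and stratified
    (Mantel-Haenszel and treated-weighted) odds-ratio comparisons of
    mobile fractions between treatments. A seeded synthetic-data module
    generates immobile, Brownian, fractional-Brownian and two-state
    trajectory ensembles and rendered spot movies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    mclust,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
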