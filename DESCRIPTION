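Package: secchimatch
Title: Matchup Validation of Citizen-Science Secchi Depths Against
    Satellite Ocean-Colour Chlorophyll
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for validating seafarer Secchi-disk transparency
    measurements against satellite ocean-colour chlorophyll-a products.
    Reads and quality-flags citizen-science Secchi observations, locates
    each observation in an equal-angle Level-3 chlorophyll composite
    (1-day or 8-day) with single-pixel or 3x3-kernel extraction, converts
    chlorophyll to an estimated Secchi depth through a calibratable
    log-polynomial bio-optical model, annotates records with bathymetry
    and distance-to-coast by inverse-squared-distance interpolation, and
    computes the log-space correlation, regression, prediction-interval
    and residual-partition statistics of the validation. A seeded
    synthetic-world generator (spatially autocorrelated chlorophyll
    fields, coastline with depth and distance grids, vessel-track
    observations with observer noise and coastal contamination) makes
    every stage testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
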