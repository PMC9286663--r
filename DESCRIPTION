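Package: brdfcorr
Title: Group-Level Kernel-Driven BRDF Correction for Airborne Imaging
    Spectroscopy Flightlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects bidirectional reflectance distribution function (BRDF)
    effects in groups of overlapping airborne imaging-spectroscopy
    flightlines using the Ross-Li kernel-driven semi-empirical model, with
    NDVI-stratified coefficient fitting across the whole flight box,
    coefficient smoothing across NDVI bins, standardization to a reference
    solar zenith angle, and SCS+C topographic pre-correction. Includes
    ENVI-style raster input/output, an overlap-consistency assessment
    (per-band RMSE, mean absolute deviation and regression between
    co-located pixels of adjacent lines), and a synthetic flight-box
    generator with known BRDF coefficients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
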