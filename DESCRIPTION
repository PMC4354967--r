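Package: nsensr
Title: Calibration and Nitrogen Recommendation for Tractor-Mounted Canopy
    Reflectance Sensors in Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a tractor-mounted crop canopy reflectance sensor
    ("N-sensor") against SPAD chlorophyll-meter readings in wheat field
    trials and turns the calibration into in-season variable-rate nitrogen
    recommendations. Implements the sensor footprint geometry, NDVI and
    sufficiency-index computation against a well-fertilized reference,
    ordinary least-squares fitting of the quadratic SPAD sufficiency-index
    response to applied N and of the linear sensor-to-SPAD bridge, the
    closed-form parametric recommendation algorithm
    N_app = R * sqrt(SI_R - SI_sensor), a sensor-value (SN) lookup
    recommendation mode, Pearson correlation and polynomial trend analysis
    of sensor attributes against laboratory N, chlorophyll and grain yield,
    and a synthetic randomized-complete-block trial generator so the whole
    chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
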