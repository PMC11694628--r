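Package: drivegrid
Title: Grid-Index Spatial Deep Learning for Driver Classification from GPS Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies drivers as normal or abnormal (mild-cognitive-impairment-like)
    from second-by-second GPS telemetry. Extracts haversine distance, central-difference
    speed, speed over ground and unit-circle direction features; segments trips with a
    sliding time window; rasterizes each segment to a translation- and rotation-invariant
    binary occupancy grid; and fuses a tabular feature stream with a convolutional grid
    stream in a compact two-stream neural classifier trained with Adam and cross-entropy.
    Includes a synthetic telematics cohort simulator, driver-grouped cross-validation,
    and data-size/width/depth experiment sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
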