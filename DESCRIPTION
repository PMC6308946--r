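Package: firegrade
Title: Forest Fire Weather Grades from Field Station Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes daily forest fire weather grades (I-V) from
    fixed-cadence environmental station time series. Replaces the
    step-interval scoring of the operational fire-danger standard with
    fitted logistic index curves, adds a litter-layer (humus) soil
    moisture correction, aggregates 10-minute sensor records into the
    daily inputs the index equations consume, and classifies each day
    onto the five-grade scale. Ships a stochastic station-weather
    generator and a fixed-size telemetry frame codec with a lossy
    channel simulator so the whole pipeline can be exercised without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
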