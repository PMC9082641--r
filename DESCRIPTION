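Package: helistroke
Title: Prehospital Stroke Transport Strategies and Helicopter Fleet Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models prehospital time chains for suspected large-vessel
    occlusion stroke in intermediate-density regions. Generates synthetic
    country-scale geographies (municipalities, stroke centres, helicopter
    bases), composes onset-to-thrombolysis and onset-to-thrombectomy times
    under four transport strategies (drip-and-ship versus direct bypass to a
    comprehensive stroke centre, by ground or by helicopter), runs a
    discrete-event simulation of helicopter fleet capacity under queueing and
    rejection policies, and computes summary tables, dispatch-pattern
    correlations, time-saved rasters and number-needed-to-fly statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
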