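Package: ortegar
Title: Time-Geographic Interaction Analysis of Animal Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies dyadic interactions between tracked animals
    using the time-geographic ORTEGA approach. Consecutive GPS fixes are turned
    into potential path area (PPA) ellipses bounded by an exponentially weighted
    moving average speed limit; spatially intersecting PPA pairs across two
    individuals are classified as concurrent or delayed by their start-time lag,
    chained into continuous interaction segments, and summarised as monthly
    frequencies and durations, home-range (95% convex hull) overlaps, movement
    parameter difference descriptors, and multi-individual interaction networks.
    Includes the classical proximity buffer-and-time-window baseline with a
    Mann-Whitney comparison harness, and a correlated-random-walk simulator with
    scripted interaction regimes that provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    xml2,
    optparse
Config/testthat/edition: 3
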