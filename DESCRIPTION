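Package: pirroutines
Title: Behavioral Pattern Analysis for In-Home PIR Motion-Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for passive-infrared (PIR) motion-sensor event
    logs collected in single-occupant homes, aimed at ambient-assisted-living
    studies of older adults. Converts point firing events into inferred
    room-occupancy timelines via a same-room gap-filling rule, computes hourly
    activity profiles and room-usage statistics, clusters daily activity
    profiles with K-means under silhouette-based model selection, and detects
    per-day wake-up and bedtime events with simple threshold rules. Includes a
    semi-Markov synthetic-resident simulator with planted wake/bed times and
    two behavioral archetypes so every stage of the pipeline can be validated
    against known ground truth.
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
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
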