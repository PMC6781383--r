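Package: tripwalk
Title: Walking Physical Activity in Trips from GPS, Accelerometer, and
    Mobility-Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measurement chain for transport-related walking built from three
    joint data streams: GPS point tracks, waist-worn accelerometer epochs, and
    a prompted-recall mobility survey.  Raw GPS streams are speed-filtered,
    segmented into visited places and trips, decomposed into unimodal trip
    stages, and assigned travel modes from speeds, habitual-mode priors and
    transit-station proximity.  A survey-reconciliation step confirms, corrects
    and recreates trips against recall, yielding a validated timetable of
    visits, trip stages and transfers from which distance walked, step counts,
    walking intensity and mode-attribution shares are computed, together with
    an algorithm-versus-survey accuracy comparison.  A seeded synthetic-world
    generator (zones, street grid, transit network, diaries, sensor artefacts)
    stands in for confidential cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
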