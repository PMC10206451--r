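Package: fishwolf
Title: Detecting and Quantifying Pulsed Fishing Behaviour by Wolves from
    GPS Telemetry and Camera Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing short-pulse fishing behaviour by grey
    wolves from GPS-collar telemetry, remote-camera records and
    camera-collar video tallies. Implements anchor-rule GPS-cluster
    detection, evidence-based classification of clusters as fishing
    sites, gap-rule segmentation of camera-trap records into events with
    ethogram summaries, inference of per-wolf fishing periods,
    buffer-occupancy indices around fishing water sources with
    before/during/after phase comparisons, hourly and seasonal activity
    profiles, and a seeded synthetic-data generator (two-state movement
    model with nocturnal creek-side bouts) so every pipeline stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
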