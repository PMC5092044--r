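Package: ecohab
Title: Analysis of RFID-Tracked Group-Housed Mouse Social Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated home-cage social-behavior phenotyping of
    group-housed mice tracked by RFID antennas in a four-compartment
    circular apparatus. Parses raw tab-separated antenna event logs,
    reconstructs per-mouse compartment visits ("sessions") with a pairwise
    event-classification algorithm, masks sessions by named experiment
    phases, and computes the standard behavioral measures: per-compartment
    occupancy, activity, pairwise time together, the in-cohort sociability
    score (observed time together minus the time expected under independent
    exploration), the approach-to-social-odor ratio, quality-control
    exclusions, and tube-dominance winning scores. A continuous-time
    movement simulator on the apparatus graph, with pairwise affinity,
    odor-driven compartment preference and an imperfect-detection model,
    generates ground-truth data so every stage is validated without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
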