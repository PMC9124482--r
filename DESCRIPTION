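Package: gardeneel
Title: Flume Foraging Analysis for Anchored Garden Eels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse flume feeding trials of burrow-anchored garden
    eels: direct linear transformation (DLT) camera calibration, projection and
    multi-view triangulation of body points; strike kinematics (strike
    distance, time, speed in earth and water frames, reactive distance) and
    vectorial dynamic body acceleration (VeDBA) from 60 Hz tracks; a
    segmented-cylinder cross-flow drag model with counterfactual posture
    scenarios; a prey-flux foraging model with a semicircular feeding area
    radiused by the third quartile of body length out of the burrow; flume
    trial bookkeeping (water cycles, release counts, control-loss corrected
    feeding rates); and synthetic-data generators (swaying eel polylines with
    strikes, advected prey particles, noisy multi-camera observations, Poisson
    trial counts) that make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
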