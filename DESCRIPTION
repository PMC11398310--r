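Package: ymaze
Title: Spatiotemporal Analysis of Locomotor Turn Decisions in Y-Maze Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how predictable an animal's upcoming turn decision is
    from its trajectory while it traverses an arm of a Y-shaped maze. Raw
    centroid tracks are segmented into bottom-arm trials, normalized to signed
    arm-relative coordinates and relative time, and summarized as Turn
    Predictiveness Index (TPI) curves in spatial and temporal bins,
    midline-crossing parity statistics (PEven), last-midline-crossing
    distributions, wall-proximity (MAD) scores, and occupancy and velocity
    fields. Includes agent-based trajectory simulators (Brownian, heading
    random walk, wall-following) and a parametric trial sampler with
    controllable crossing-parity bias, plus resampling null models for
    crossing sequences, so every analysis stage can be exercised on synthetic
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
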