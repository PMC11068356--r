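Package: reachrefine
Title: Quantifying Motor Skill Refinement from Reach Trajectories and
    Cortical Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-pellet reaching experiments with
    head-mounted miniscope calcium imaging. Quantifies reach-trajectory
    variability via pairwise Hausdorff distances, detects calcium events in
    scaled fluorescence traces (3x baseline-SD rule with rising-phase
    extraction), classifies movement-related neurons by a rank-sum test
    against per-trial movement windows, computes peri-movement population
    activity (activated = peak minus baseline) and trial-to-trial population
    vector correlations, tabulates behavioral outcome rates, and normalizes
    fEPSP amplitude series to percentage of baseline around high-frequency
    stimulation. Includes a seeded synthetic-session generator emulating the
    statistical structure of such recordings so every stage is testable
    without animal data.
License: MIT
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
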