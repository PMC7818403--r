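Package: numact
Title: Cross-Validated Voxel Analyses of Action-Numerosity fMRI Block Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for featural-attention fMRI block
    designs probing the numerosity of observed manipulative actions. Generates
    counterbalanced factorial stimulus schedules, simulates voxel populations
    with known numerosity tuning and HRF-convolved BOLD time series, fits
    per-run GLMs and converts betas to percent signal change relative to
    active fixation, recodes conditions into cross-validated preferred and
    non-preferred responses over all selection/evaluation run splits, runs
    ROI-level 2x2 repeated-measures ANOVA with Holm step-down correction,
    computes single-voxel dAction/dBall selectivity with a shuffled null
    distribution of the below-diagonal proportion, and performs
    leave-one-run-out linear SVM decoding of action numerosity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
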