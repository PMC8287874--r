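Package: stereodepth
Title: Stereoscopic Depth Psychophysics and fMRI Decoding Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how object context modulates stereoscopic
    depth processing. Synthesizes disparity-defined random-dot stereograms
    from depth maps (upright, inverted, and phase-scrambled surfaces) with
    controlled signal-to-noise ratio; runs QUEST Bayesian adaptive
    staircases with simulated Weibull observers; generates synthetic
    block-design fMRI datasets with known multivoxel ground truth; fits
    boxcar-convolved two-gamma GLMs; performs leave-one-run-out linear SVM
    decoding with recursive feature elimination, block-level permutation
    baselines, and searchlight mapping; and provides repeated-measures
    ANOVA, Bonferroni post hoc tests, and brain-behavior correlation
    analyses. All results are returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
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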