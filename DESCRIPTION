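Package: postprime
Title: Fear-Priming Step-and-Reach Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of fear-primed step-and-reach trials recorded
    with multi-rate laboratory channels (16-channel surface EMG at 2000 Hz,
    dual tri-axial force plates at 1000 Hz, whole-body kinematics at 100 Hz,
    and a binary reach sensor). Implements the full chain from raw channels to
    group statistics: Savitzky-Golay kinematic smoothing, mains-notch /
    rectify / zero-lag Butterworth EMG envelopes with per-participant
    normalization, threshold-based detection of reach, center-of-pressure and
    step events, muscle-onset detection (sustained supra-threshold rule) and
    phase-windowed co-contraction indices, preparatory and total
    center-of-mass and joint-excursion metrics, and a two-way mixed
    repeated-measures ANOVA layer with Greenhouse-Geisser correction, partial
    eta squared, family-wise alpha adjustment and Bonferroni post hocs. A
    synthetic cohort generator with known ground truth reproduces the study
    design (two age groups, four blocked surface conditions, three trials
    each) so every stage is testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
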