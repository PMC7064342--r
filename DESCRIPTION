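Package: landmarkCoding
Title: Landmark-Anchored Spatial Coding Analysis for Virtual-Reality
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for head-fixed virtual-reality linear-track
    experiments with two-photon calcium imaging. Provides an S4 session
    container built on SummarizedExperiment binding frame-resolved behavior,
    a trial table, and ROI fluorescence traces; delta-F/F baseline estimation
    and calcium-transient detection in time and anchor-aligned space;
    behavioral task metrics (first-lick statistics, task score, spatial
    modulation z-score); classification of neurons by their anchoring task
    feature (trial onset, landmark, reward) with shuffle-based engagement
    testing; a template-matching trial-type decoder; split-half population
    vector cross-correlation and location reconstruction; visuo-motor
    integration tests in a decoupled (open-loop) stimulus condition; and a
    seeded synthetic-session generator with ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
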