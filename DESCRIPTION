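Package: wormspan
Title: Longitudinal Behavioral Phenotyping, Lifespan and Healthspan Analysis
    for Chamber-Housed C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Off-line analysis pipeline for long-term single-worm culture
    imaging. From grayscale clips of individually housed C. elegans in
    circular microfluidic chambers it locates chambers, segments the worm
    with a consensus of thresholding candidates filtered by positional and
    morphological priors, and extracts four behavioral metrics per clip:
    raw movement (frame-difference pixel fraction), centroid speed,
    body-bend amplitude and swimming frequency. Longitudinal traces are
    scored for death by a two-day movement-cessation rule, classified into
    high/low-activity phases (k-means or moving-average), summarized as
    healthspan statistics, compared across cohorts and conditions
    (Kaplan-Meier, log-rank, ANOVA/Tukey, Kolmogorov-Smirnov, Pearson), and
    used to predict individual lifespan with cross-validated LASSO
    regression. A synthetic-data generator renders ground-truthed worm
    clips and aging cohorts so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    survival,
    glmnet,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
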