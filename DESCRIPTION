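Package: remoteaffect
Title: Remote Detection of Stress and Boredom in Gaming Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A user-tailored pipeline for detecting emotional states of
    stress and boredom from video-derived signals recorded during gaming
    sessions. Per-frame facial-activity features are computed from
    68-point facial landmark tracks, and heart rate is estimated from
    mean-RGB pixel traces with a blind-source-separation remote
    photoplethysmography (rPPG) method. Calibration-game recordings are
    segmented into boring and stressful parts that label training data
    for a per-subject neural network, which is then evaluated either by
    leave-one-session-out cross-validation or on an independent
    evaluation game whose test labels derive from Likert self-reports.
    Includes exact binomial chance-level calibration, Wilcoxon
    signed-rank comparisons, and a synthetic session generator that
    emulates every input so the whole pipeline is testable end to end.
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
    nnet,
    pROC,
    purrr,
    rlang,
    signal,
    stats,
    grDevices,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
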