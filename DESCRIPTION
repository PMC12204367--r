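Package: abrtools
Title: Automated Analysis of Auditory Brainstem Response Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for automated analysis of auditory brainstem response (ABR)
    recordings from rodent hearing studies. Provides readers for wide and long
    waveform tables, resampling onto a canonical 244-point/10 ms grid, waveform
    and stack scaling, Gaussian smoothing, a two-step wave 1-5 peak and trough
    detector (1-D convolutional network latency regression followed by
    local-extremum refinement), supervised hearing-threshold estimation with
    three classifier families, elastic time warping for cross-level alignment,
    a seeded synthetic ABR simulator with ground truth, and training and
    evaluation machinery (subject-level splits, per-source loss weighting,
    augmentation, early stopping, ROC/PR metrics, bootstrap intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
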