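Package: ppgbp
Title: Cuffless Blood-Pressure Estimation from Photoplethysmogram Images
    with Multi-Head Cross-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates systolic and diastolic blood pressure from a
    single-site photoplethysmogram (PPG). The signal and its first (vPPG)
    and second (aPPG) derivatives are band-pass filtered, segmented into
    overlapping windows, rasterized into fixed-size images, and mapped to
    spatial feature tokens by a convolutional backbone. Tokens from the
    three modalities are fused with multi-head cross-attention (PPG as
    query, vPPG as key, aPPG as value) and regressed onto blood pressure.
    Includes a seeded synthetic-PPG simulator with a documented
    morphology-to-pressure link, end-to-end training with k-fold
    cross-validation, and clinical-grade evaluation: R-squared, RMSE, MAE,
    mean error and its standard deviation with bootstrap confidence
    intervals, Bland-Altman agreement, AAMI compliance and BHS grading.
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
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
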