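Package: ctgnet
Title: Cardiotocogram Classification with Compact Convolutional and
    Recurrent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying intrapartum cardiotocograms (paired
    fetal-heart-rate and uterine-contraction recordings) by postnatal
    outcome. Implements trace quality control (signal-loss accounting,
    last-window extraction, downsampling to 1 Hz), a cohort sorting
    pipeline driven by umbilical-artery pH and 1-min Apgar score, a
    conventional feature pipeline (spike removal, moving-average
    smoothing, Hilbert-envelope episode detection, acceleration counts
    and deceleration areas) with SVM and k-means baselines, a compact
    three-layer depthwise-separable convolutional network trained with
    Adam, a dual next-step-prediction LSTM risk index, and an
    evaluation layer (precision/recall/F1, threshold-sweep ROC-AUC,
    tenfold cross-validation with normal-group resampling, multi-seed
    repetition and model comparison tests). A bundled simulator
    generates cardiotocograms with annotated accelerations and
    decelerations plus matching clinical registries so the whole stack
    is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
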