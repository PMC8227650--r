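Package: edapain
Title: Real-Time Electrodermal Activity Indices for Acute Pain Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for objective, near real-time detection of acute pain from
    electrodermal activity (EDA). Implements the preprocessing chain (cubic-spline
    resampling, median filtering, high-pass filtering at 2 Hz), variable frequency
    complex demodulation (VFCDM) time-frequency decomposition, a convex-optimization
    tonic/phasic decomposition with a sparse nonnegative sudomotor driver, and three
    real-time indices: the time-varying sympathetic index (TVSymp), its modified form
    (MTVSymp), and the derivative of the phasic component (dPhEDA). Includes a
    streaming windowed computation scheme, stimulus-locked segment feature extraction,
    discriminability statistics (Fisher's ratio, AUROC with stratified bootstrap,
    subject-nested permutation rank test), a leave-one-subject-out machine-learning
    evaluation harness, and a synthetic EDA generator with known tonic/phasic ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    quadprog,
    randomForest,
    readr,
    rlang,
    rpart,
    signal,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
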