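Package: vibroscreen
Title: Vibration-Imaging and Dual-Risk Screening for Depression and Anxiety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for head-neck micro-vibration screening studies: per-pixel
    amplitude and dominant-frequency maps from grayscale video, a compact
    CNN-BiLSTM dual-risk scorer with temperature-scaling calibration and
    Youden-index three-tier stratification, Zung SDS/SAS scale scoring with
    Chinese-norm categories, keyword-based dual-axis clinical severity
    quantification, and a full diagnostic-accuracy toolkit (confusion-matrix
    metrics, ROC/AUC, bootstrap confidence intervals, decision-curve analysis,
    and logical-OR combined-screener gain analysis). Ships a synthetic-data
    generator emulating the statistical structure of a screening cohort so the
    whole pipeline is testable without patient data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
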