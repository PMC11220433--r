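Package: pvsignal
Title: Pharmacovigilance Signal Detection for Annotated Social-Media Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for drug-safety signal detection on
    drug / adverse-drug-event (ADE) annotation corpora extracted from
    web forums and normalized to ATC and MedDRA codes. Provides CSV
    input/output and filtering for per-post annotation tables,
    descriptive statistics (per-forum cumulative frequencies, preferred-term
    rankings, monthly series), disproportionality analysis (proportional
    reporting ratio and reporting odds ratio with Wald confidence
    intervals on the log scale and the lower-bound signal rule), a
    class-imbalanced subsampling lasso for multivariate signal detection,
    CUSUM change-point segmentation with permutation-bootstrap
    significance, and a synthetic corpus generator with designed
    drug-ADE association strengths and temporal rate shifts for
    offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
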