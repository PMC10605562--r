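Package: nmics
Title: Identification and Analysis of Non-Medically Indicated Caesarean
    Sections in Hospital Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A claims-data phenotyping pipeline for planned caesarean
    sections performed without medical indication (nmi CS) in Swiss
    hospital discharge data (SwissDRG, ICD-10-GM, CHOP). Provides a
    year-aware codebook of DRG target codes and diagnosis/procedure
    exclusion patterns, a gated cohort-selection classifier, annual
    summary arithmetic, descriptive group comparisons (t-tests, Spearman
    rank correlation), a logistic regression of birth mode on maternal
    and cantonal factors fitted by iteratively reweighted least squares
    with Wald intervals and ROC/AUC, and a seeded synthetic
    discharge-record generator that embeds the fitted model as ground
    truth so that the whole pipeline is testable without the
    restricted-access national dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
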