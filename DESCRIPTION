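Package: evidencegrader
Title: Distant Supervision and Prediction of GRADE Certainty of Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quality-of-evidence datasets from structured systematic-review
    records by distant supervision: GRADE downgrading reasons are recovered from
    summary-of-findings footnotes via a term lexicon, checked against the overall
    grade by the GRADE step arithmetic, and filtered for consistency; filtered-out
    instances with detected reasons are recycled as partially labeled supplements.
    Includes alignment of bodies of evidence to primary studies by constrained
    edit-distance matching, a synthetic review-corpus generator with planted,
    configurable signal for every downgrading criterion, a multi-view neural
    classifier over numeric, categorical and hashed-text features with binary,
    multilabel, multiclass and regression heads, trivial and logistic-regression
    baselines, and grouped cross-validation with closed-form expected metrics for
    the trivial baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
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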