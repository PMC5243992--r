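Package: crowdtma
Title: Crowdsourced Scoring of Tissue Microarrays: Consensus, Agreement
    and Group-Size Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse crowdsourced scoring of cancer tissue
    microarrays (TMAs). Simulates grid-based cancer-detection annotations
    and immunohistochemistry (IHC) proportion/intensity ratings from
    heterogeneous lay raters and small expert panels, forms majority-vote
    and median consensus scores, computes agreement statistics
    (sensitivity, specificity, F1, Cohen's kappa, ROC AUC, Spearman rank
    correlation of H-scores), bootstraps the relationship between crowd
    size and accuracy with percentile confidence intervals, and fits the
    2x2 factorial linear model for the effect of tutorial components on
    individual performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
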