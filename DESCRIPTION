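Package: modulearn
Title: Stability-Selected Classification of Mental-Training Effects on
    Psychological Distress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for randomized mental-training studies that ask
    which facets of self-reported psychological distress respond to which
    3-month training module. Builds episode-level change-score datasets over a
    68-variable, 16-questionnaire distress panel, trains four classifier
    families (logistic regression, random forest, a boosted sum-of-trees
    ensemble, and the elastic net) under repeated group-aware stratified
    10-fold cross-validation, tests balanced accuracy against chance with a
    Wilcoxon signed-rank test, runs a four-stage majority-vote and bootstrap
    forward/backward stability selection with a 95 percent selection-rate
    replicability criterion, and converts selected variables into
    module-specific effect profiles (logistic coefficients,
    improvement-oriented Cohen's d and one-sided Welch tests against the other
    module and a retest control cohort). Includes a synthetic generator for
    correlated questionnaire change scores with planted module-specific
    effects, so the full pipeline is testable when the original study data
    cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
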