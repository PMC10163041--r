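Package: painsex
Title: Sex Inference from Multivariate Pain-Threshold Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning workflow for deciding whether a person's sex can
    be inferred from quantitative sensory testing (QST) pain thresholds, which
    threshold variables carry that information, and whether the remaining
    variables demonstrably carry none. Implements a seeded synthetic-cohort
    generator with log-normal thresholds, device censoring and von Frey
    quantisation; distribution-optimal class-proportional train/validation
    splitting; a 26-method feature-selection vote matrix built in repeated
    stratified cross-validation; computed ABC (cABC) item categorisation with
    a recursive variant; five classifier types including a small deep neural
    network; and a 100-run validation experiment with permutation and
    unselected-feature negative controls evaluated by balanced accuracy and
    ROC-AUC with nonparametric confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
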