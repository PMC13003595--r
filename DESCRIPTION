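Package: hibpn
Title: Bidirectional Prediction of Social Exclusion and Hostile Interpretation Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the Hostile Interpretation and Bidirectional Prediction
    Network (HIBPN), a modular multilayer perceptron that predicts social
    exclusion state from trait and cognition features (forward chain) and
    hostile-interpretation bias from trait and situation features (reverse
    chain). Includes psychometric scoring of the NPI-16, Hypersensitive
    Narcissism Scale, Basic Needs Scale and ambiguous-sentence interpretation
    ratings; a synthetic cohort generator emulating Cyberball social
    exclusion/acceptance experiments; ten classical baseline classifiers;
    classification metrics (accuracy, F1, ROC/AUC); module ablation; grouped
    random-forest feature importance; and a self-affirmation intervention
    contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    readr,
    jsonlite,
    randomForest,
    e1071,
    MASS,
    class,
    rpart,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
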