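Package: fedtan
Title: Federated Tree-Augmented Naive Bayes for Categorical Incident Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for training Tree-Augmented Naive Bayes (TAN) classifiers
    on categorical incident records that are horizontally partitioned across
    data stations which may not move raw records. Stations exchange only
    class-conditional sufficient statistics with a coordinator; because these
    counts are additive, the pooled model is exactly the model that would
    have been trained on the pooled data. Includes schema harmonization
    across stations with heterogeneous class spaces, CSV and minimal RDF
    ingestion, a synthetic scenario generator emulating a three-station food
    fraud surveillance network, multiclass evaluation (one-vs-rest
    sensitivity and specificity, micro-average ROC/AUC), and harnesses
    comparing per-station, combined-federated and centralized training.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
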