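Package: hullshift
Title: Convex-Hull Coverage and Classifier-Based Detection of Dataset Shift
    Between Multi-Site Patient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies heterogeneity between tabular patient cohorts of
    different origin (for example, different hospitals) with a two-step
    pipeline. Step one measures, for every ordered pair of sites and every
    pair of numeric features, the fraction of one site's patients that fall
    inside the 2D convex hull of the other site's patients, with DBSCAN
    denoising of the hull-forming sample and bootstrap averaging; per-feature
    median coverages are aggregated to a site-by-site mean-coverage matrix
    and features with anomalously low coverage are flagged by a
    Q1 - 1.5*IQR rule. Step two trains classifiers (logistic regression,
    random forest, support vector machine, AdaBoost) to discriminate the
    site of origin of a sample, before and after removing the flagged
    features. A cross-site generalization harness labels first-day ARDS from
    diagnosis codes plus a sustained Horowitz-index (PaO2/FiO2) drop, trains
    one random-forest endpoint model per site, and evaluates every model on
    every site. A seeded generator of synthetic multi-site cohorts with
    controllable support shift, cluster-gap structure, missingness and
    endpoint prevalence makes the whole pipeline testable without clinical
    data.
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
    MASS,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    e1071,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    arrow,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
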