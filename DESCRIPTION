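Package: impbench
Title: Benchmarking Imputation Methods Under Outliers and Misclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for measuring how the quality of missing-value
    imputation degrades when data are contaminated by high-leverage outliers
    or misclassified categories. Provides a mixed-type data model with
    per-column scale declarations, MCAR/MAR amputation with robust
    (MCD-based) outlier protection, two synthetic study populations
    (a bivariate Gaussian age/income population and a lognormal
    energy-consumption model), a range of imputers (mean/median/mode, random
    hotdeck, Gower-distance k-nearest-neighbour, Bayesian-regression
    predictive mean matching, midastouch distance-weighted donor sampling,
    iterative robust model-based imputation, iterative random-forest and
    bootstrap boosted-tree imputation), evaluation statistics (MAPE, NRMSE,
    correlation distortion, false classification rate, loading differences,
    bias/variance/RMSE, coverage rates, Rubin pooling, F1/accuracy), and
    config-driven simulation-study harnesses with common random numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    nnet,
    ranger,
    xgboost,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
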