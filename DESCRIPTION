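Package: boostmec
Title: Boosted Variable Selection for Misclassified Binary Responses and
    Error-Prone Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection and estimation for logistic and probit
    regression when the binary response may be misclassified and the
    (possibly ultrahigh-dimensional) continuous predictors carry classical
    additive measurement error.  Measurement error in the response is
    corrected through the inverse of the 2x2 misclassification matrix;
    error in the predictors is corrected through a sufficient-statistic
    substitution (logistic) or regression calibration (probit).  The
    corrected estimating functions drive a thresholded boosting procedure
    that selects informative predictors and estimates their coefficients
    simultaneously.  Includes a synthetic-data generator, a replicated
    simulation-study driver with estimation-error and selection metrics,
    and a sensitivity-analysis workflow over the measurement-error
    variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
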