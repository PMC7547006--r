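Package: locustgam
Title: Daily Locust Abundance Modelling with Negative Binomial GAMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models daily density of the Australian plague locust
    (Chortoicetes terminifera) from roadside survey records and gridded
    environmental covariates. Implements the full pipeline: stochastic
    conversion of ordinal density classes to continuous abundance, rolling
    10/60-day weather covariates with threshold-day counts, GLM/lasso/ridge/
    stepwise-AIC feature selection with t-statistic variable importance,
    a negative binomial square-root-link GAM with a longitude-latitude-
    day-of-year tensor smooth, holdout/cross-validation evaluation, and
    gridded abundance maps with combined model and class-sampling
    uncertainty, a 50-km survey-proximity mask, and bivariate
    density/uncertainty classes. A synthetic-data generator emulates the
    survey and gridded-weather inputs so that every stage is testable
    without proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    glmnet,
    MASS,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
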