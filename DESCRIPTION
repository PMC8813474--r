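Package: delivcov
Title: Bayesian Trend Modelling and Inequality Analysis of Delivery-Care
    Coverage Among Adolescents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and projecting coverage of institutional
    delivery (INSD) and skilled birth attendance (SBA) among adolescent
    mothers from multi-country household-survey series. Fits a Bayesian
    hierarchical binomial-logit trend model with country random intercepts
    and slopes and optional Sociodemographic Index and health-workforce
    covariates, projects coverage to 2030 with credible intervals, computes
    Gelman-Rubin convergence diagnostics, wealth-based inequality via the
    slope index of inequality, urban-rural gaps, and a random-intercept
    logistic model of individual-level determinants. Includes a synthetic
    survey-data generator with known ground truth for end-to-end validation
    and a packaged table of published national predictions for threshold
    reporting.
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
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
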