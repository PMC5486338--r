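Package: staqr
Title: Structured Additive Bayesian Quantile Regression for Childhood Anemia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits structured additive quantile regression models for childhood
    hemoglobin concentration by Gibbs sampling under the asymmetric Laplace
    working likelihood. The additive predictor combines categorical fixed
    effects, second-order random-walk (P-spline type) smooths of continuous
    covariates, and an intrinsic conditional autoregressive (Besag) spatial
    effect over administrative districts, with deviance information criterion
    model comparison. Includes exploratory cross-tabulation tools for anemia
    prevalence, an exact linear-programming-type frequentist quantile
    regression solver used as an oracle for the sampler, adjacency graph
    utilities, and a calibrated generator of synthetic Demographic and Health
    Survey style child records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
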