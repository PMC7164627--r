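Package: stgmm
Title: Class Enumeration in Skew-t Family Growth Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying over-extraction of latent classes in growth
    mixture models (GMMs) built on the restricted multivariate skew-t family of
    distributions (normal, skew normal, t, skew t). Provides a linear latent
    growth model with implied-moment computation, a Fleishman/Vale-Maurelli
    generator for nonnormal longitudinal data with target marginal skewness and
    excess kurtosis, maximum-likelihood estimation of K-class skew-t family
    GMMs by an EM algorithm with a compiled core, class-enumeration criteria
    (AIC, BIC, sample-size-adjusted BIC, Vuong-Lo-Mendell-Rubin and
    Lo-Mendell-Rubin adjusted likelihood ratio tests, parametric bootstrap
    likelihood ratio test), and a Monte Carlo driver that estimates
    false-positive (over-extraction) rates and convergence rates over a
    factorial simulation design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
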