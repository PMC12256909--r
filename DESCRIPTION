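Package: pgsqr
Title: Quantile-Regression Screening of Polygenic Score Predictive Heterogeneity
Version: 1.0.0
Authors@R:
    person("pgsqr", "maintainers", email = "pgsqr@example.org", role = c("aut", "cre"))
Description: Screens trait-polygenic-score pairs for substantial heterogeneity of
    predictive value across the phenotypic range. Covariates are projected out of
    both trait and score, quantile regression estimates quantile-specific effect
    sizes over a grid of quantiles, an m-of-n bootstrap estimates the joint
    sampling covariance of the ordinary-least-squares and quantile-specific
    effects, and non-equivalence (minimum-effects) tests flag quantiles whose
    effect-size ratio falls outside a practical equivalence band. Linear and
    quadratic trend meta-regressions and a crossing-quantile summary aid the
    interpretation of gene-by-environment signatures. A simulator generates
    synthetic cohorts with coordinated gene-by-environment interactions and a
    two-half GWAS-to-score design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
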