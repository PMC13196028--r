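Package: lysogrow
Title: Growth Dynamics of Surviving Bacteria After Phage-Mediated Lysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consumer-resource modelling and analysis of how phage-mediated
    lysis of a lysogen subpopulation transiently boosts the growth of the
    surviving cells. Provides a Monod-based ODE model of wild-type and
    temperature-sensitive lysogens with Erlang-distributed (linear-chain)
    lysis timing and lysate recycling; a three-stage weighted nonlinear
    least-squares parametrization of the model from replicate OD600 growth
    curves with bootstrap confidence intervals; a mother-machine single-cell
    growth-rate pipeline (log-length regression, quality filters, two-way
    ANOVA with Tukey HSD on replicate means); and seeded synthetic-data
    generators for both batch growth curves and single-cell track cohorts so
    the entire analysis is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
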