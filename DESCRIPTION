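Package: lexdrift
Title: Iterated-Learning Simulation of Lexically Diffusing Sound Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates articulatorily-motivated sound change as an
    iterated-learning process over a word-frequency lexicon. Each
    generation's corpus of reduced/unreduced token counts is produced by a
    logistic generative model in which reduction pressure grows with usage
    frequency, and is relearned by a hierarchical learner: a binomial
    mixed model with a by-word random intercept, fitted by maximum
    likelihood with adaptive Gauss-Hermite quadrature. Provides
    constraint-matched skewed-lexicon generation, chain and ensemble
    runners with stopping rules and outcome classification (sputtered,
    completed, stable polarized variation), and the diagnostics used to
    study lexicalization: frequency-effect curves, U-shape detection,
    variance explained by (log) frequency, reduction-probability
    distribution tables, random-effect radicalization traces, and exact
    outcome comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
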