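Package: wingrn
Title: Module-Anchored Inference of Gene Regulatory Networks from
    Time-Series Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers sparse directed gene regulatory networks from short
    time-series expression profiles by sliding a three-gene window across
    the gene set. Within each window, small linear ordinary differential
    equation models of candidate regulatory structures (parallel fan-out,
    serial cascade, convergent fan-in, null) are fitted by nonlinear least
    squares and compared with a sum-of-squared-error based Bayesian
    information criterion; windows migrate by a one-gene-in one-gene-out
    rule ranked on Spearman correlation, and activation lags order
    regulators before targets. Includes a ground-truth simulator for
    cascade networks, DREAM-style gold-standard evaluation (confusion
    counts over undirected gene pairs, sensitivity, specificity, positive
    predictive value, and an exact hypergeometric random-guess baseline),
    and tidy accessors and plots for every result type.
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
    purrr,
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
    igraph,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
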