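Package: dpkf
Title: Dirichlet Process Kalman Filter Models of Memory Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling human memory updating as Bayesian filtering in
    a switching linear-Gaussian state space with an unbounded number of
    dynamical modes. Provides the sticky Chinese-restaurant-process generative
    model and simulator, the Dirichlet-process Kalman filter (DP-KF) with a
    local single-partition (hard MAP assignment) approximation, within-mode
    Rauch-Tung-Striebel smoothing for memory reconstruction, a generator for
    the gradual/jump line-segment prediction task, maximum-likelihood fitting
    of four nested model variants with random restarts and cross-validated
    model comparison, and the accompanying behavioural analyses (reconstruction
    distance statistics, repeated-measures ANOVA, Fisher-z correlations,
    inferred mode counts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
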