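Package: deckrl
Title: Reinforcement-Learning Choice Models for the Iowa and Soochow Gambling Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a factorial space of 18 reinforcement-learning choice
    models for the Iowa Gambling Task (IGT) and the Soochow Gambling Task
    (SGT), combining three utility functions (weighted expected utility,
    prospect utility on net payoff, and prospect utility with separately
    evaluated gains and losses), three expectancy-updating rules (delta,
    decay-reinforcement, and a mixed decay-delta rule), and two softmax
    choice rules (trial-dependent and trial-independent sensitivity),
    including the named EVL, PVL, and PVL2 models. Provides exact encodings
    of the two tasks' payoff schedules with within-block randomization,
    generative simulation of synthetic agents, one-step-ahead
    maximum-likelihood fitting with a multi-start Nelder-Mead search,
    BIC-difference comparison against a constant-probability baseline,
    pairwise model comparison, and Spearman rank tests of cross-task
    parameter consistency.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
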