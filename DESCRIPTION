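Package: cuematch
Title: Probability Matching by Logistic Perceptrons Under Multi-Cue Reward
    Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reinforcement training of single-output logistic
    perceptrons on stochastic multi-cue reward schedules and measures how
    closely their responses match conditional reward probabilities. Provides
    a synthetic-data generator for four-cue binary reward worlds (independent
    cue lotteries, optional AND/XOR interaction gates, no-cue baseline), a
    per-pattern delta-rule trainer with trajectory recording, probability-
    matching and logistic-regression-equivalence diagnostics, a reward-
    stratified chi-square measure of conditional dependence between cues,
    and orchestration for full factorial simulation experiments with ANOVA
    and regression summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
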