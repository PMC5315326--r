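# Fixtures built in code: hand-constructed training sets with exact
# per-configuration reward counts, and the worked-example response table.

# A training_set whose observed reward count for configuration i is
# exactly round(rates[i] * replicates); rates in enumeration order.
manual_training_set <- function(rates, replicates = 100,
                                model = sim1_model(), seed = 0L) {
  stopifnot(length(rates) == 16)
  pats <- cue_patterns()
  rows <- do.call(rbind, lapply(seq_len(16), function(i) {
    k <- round(rates[i] * replicates)
    data.frame(a = pats[i, 1], b = pats[i, 2], x = pats[i, 3],
               y = pats[i, 4],
               target = rep(c(1L, 0L), c(k, replicates - k)))
  }))
  structure(list(rows = tibble::as_tibble(rows),
                 replicates = as.integer(replicates), model = model,
                 seed = as.integer(seed)),
            class = "training_set")
}

# A training_set holding only the given configurations (matrix rows) with
# exact reward counts; used for closed-form logistic checks.
partial_training_set <- function(patterns, rates, replicates = 100) {
  stopifnot(nrow(patterns) == length(rates))
  rows <- do.call(rbind, lapply(seq_along(rates), function(i) {
    k <- round(rates[i] * replicates)
    data.frame(a = patterns[i, 1], b = patterns[i, 2], x = patterns[i, 3],
               y = patterns[i, 4],
               target = rep(c(1L, 0L), c(k, replicates - k)))
  }))
  structure(list(rows = tibble::as_tibble(rows),
                 replicates = as.integer(replicates), model = sim1_model(),
                 seed = 0L),
            class = "training_set")
}

# The published worked example: observed reward rates of one training set
# and a typical trained network's responses, both over the 16 patterns.
worked_example <- function() {
  list(
    actual = c(0.00, 0.63, 0.64, 0.90, 0.35, 0.88, 0.81, 0.98,
               0.21, 0.79, 0.70, 0.96, 0.47, 0.94, 0.77, 0.96),
    response = c(0.12, 0.65, 0.57, 0.95, 0.32, 0.86, 0.81, 0.98,
                 0.19, 0.76, 0.69, 0.97, 0.44, 0.91, 0.88, 0.99)
  )
}
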