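#' Sample a stochastic training set from a reward model
#'
#' Draws `replicates` trials for each of the sixteen cue configurations.
#' For each trial, one uniform random number is drawn per active reward
#' source (in the fixed order A, B, X-or-gate, Y) and the trial's target is
#' 1 if any source fires (a trial is rewarded at most once), else 0. Rows
#' are emitted in enumeration order — pattern 1 block first, then pattern 2,
#' and so on; presentation order is randomized later, by the trainer, so
#' that sampling reproducibility and training reproducibility stay
#' independent. The whole draw consumes a single RNG stream seeded with
#' `seed`, so identical `(model, replicates, seed)` give identical sets.
#'
#' @param model A [reward_model()].
#' @param replicates Trials per configuration (default 100, for the
#'   standard 1600-row set).
#' @param seed Integer seed for the generation stream.
#' @return An object of class `"training_set"`: a list with `rows` (a
#'   tibble with columns `a,b,x,y,target`), `replicates`, `model`, `seed`.
#' @examples
#' ts <- generate_training_set(sim1_model(), replicates = 10, seed = 1)
#' nrow(ts$rows)  # 160
#' @export
generate_training_set <- function(model, replicates = 100, seed) {
  stopifnot(inherits(model, "reward_model"), replicates >= 1)
  replicates <- as.integer(replicates)
  seed <- as.integer(seed)
  pats <- cue_patterns()
  target <- withr::with_seed(seed, {
    unlist(lapply(seq_len(16L), function(i) {
      src <- reward_sources(model, pats[i, ])
      if (length(src) == 0L) return(rep(0L, replicates))
      # row r of the draw matrix holds trial r's draws in source order
      u <- matrix(runif(replicates * length(src)),
                  nrow = replicates, byrow = TRUE)
      as.integer(rowSums(u <= rep(src, each = replicates)) > 0)
    }))
  })
  rows <- tibble::as_tibble(pats[rep(seq_len(16L), each = replicates), ,
                                 drop = FALSE])
  rows$target <- target
  structure(
    list(rows = rows, replicates = replicates, model = model, seed = seed),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("Training set: %d rows (16 configurations x %d), seed %d\n",
              nrow(x$rows), x$replicates, x$seed))
  print(x$model)
  invisible(x)
}

#' Check a training set's reward rates against its generating model
#'
#' For each of the sixteen configurations, compares the observed
#' (reward, no-reward) counts to the expected counts \eqn{n p} and
#' \eqn{n (1 - p)} with a 1-df Pearson goodness-of-fit statistic
#' (no continuity correction); cells with expected count 0 contribute 0,
#' which only arises for expected probabilities of exactly 0 or 1, where
#' the configuration instead passes iff its observed counts are degenerate
#' in the same way.
#'
#' @param ts A [generate_training_set()] result.
#' @param alpha Significance level for the per-configuration test
#'   (default 0.05).
#' @return A tibble with one row per configuration: `pattern` label,
#'   `n`, `observed_rate`, `expected_rate`, `chi2`, `pass`.
#' @export
validate_training_set <- function(ts, alpha = 0.05) {
  stopifnot(inherits(ts, "training_set"), nrow(ts$rows) > 0)
  expected <- expected_reward_probability(ts$model)
  observed <- empirical_pattern_frequencies(ts)
  n <- ts$replicates
  crit <- qchisq(1 - alpha, df = 1)
  chi2 <- vapply(seq_len(16L), function(i) {
    p <- expected[i]
    o1 <- observed[i] * n
    gof_terms <- c(if (p > 0) (o1 - n * p)^2 / (n * p),
                   if (p < 1) ((n - o1) - n * (1 - p))^2 / (n * (1 - p)))
    sum(gof_terms)
  }, numeric(1))
  pass <- ifelse(expected %in% c(0, 1), observed == expected, chi2 < crit)
  tibble::tibble(pattern = pattern_labels(), n = n,
                 observed_rate = unname(observed),
                 expected_rate = unname(expected),
                 chi2 = chi2, pass = pass)
}

#' Generate a training set, redrawing until it validates
#'
#' Repeats [generate_training_set()] with successive seeds (`seed`,
#' `seed + 1`, ...) until [validate_training_set()] passes on every
#' configuration, mirroring an accept/reject sampling protocol. Sets at
#' these sizes almost always pass on the first draw.
#'
#' @inheritParams generate_training_set
#' @param alpha Significance level for validation.
#' @param max_attempts Give up (with an error) after this many draws.
#' @return A validated `"training_set"`.
#' @export
generate_valid_training_set <- function(model, replicates = 100, seed,
                                        alpha = 0.05, max_attempts = 20) {
  for (k in seq_len(max_attempts)) {
    s <- (as.integer(seed) + k - 1L) %% .Machine$integer.max
    ts <- generate_training_set(model, replicates, s)
    if (all(validate_training_set(ts, alpha)$pass)) return(ts)
  }
  stop("no training set passed validation in ", max_attempts, " attempts",
       call. = FALSE)
}

#' Write and read a training set as CSV plus a JSON sidecar
#'
#' The CSV holds the rows (`a,b,x,y,target`, values 0/1); the sidecar
#' `<path>.json` records the generating model, replicate count and seed so
#' the set can be reconstructed exactly.
#'
#' @param ts A `"training_set"`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_training_set` returns `path` invisibly;
#'   `read_training_set` returns the reconstructed `"training_set"`.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  write.csv(ts$rows, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    replicates = ts$replicates,
    seed = ts$seed,
    model = list(
      independent_probs = as.list(ts$model$independent_probs),
      gate = ts$model$gate,
      baseline_prob = ts$model$baseline_prob
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  rows <- tibble::as_tibble(read.csv(path))
  stopifnot(identical(names(rows), c("a", "b", "x", "y", "target")))
  rows[] <- lapply(rows, as.integer)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gate <- meta$model$gate
  model <- reward_model(
    independent_probs = unlist(meta$model$independent_probs),
    gate = if (length(gate) > 0) as.list(gate),
    baseline_prob = meta$model$baseline_prob
  )
  structure(
    list(rows = rows, replicates = as.integer(meta$replicates),
         model = model, seed = as.integer(meta$seed)),
    class = "training_set"
  )
}
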