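# Orchestration of the two simulation experiments: batches of training
# sets and networks, per-network diagnostics, and the factorial analyses.

# Draw n child seeds (below 2^31) from a master-seeded stream.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

new_experiment_result <- function(networks, sets, label) {
  summary <- do.call(rbind, lapply(split(networks, networks$condition),
    function(d) {
      tibble::tibble(condition = d$condition[1],
                     n_networks = nrow(d),
                     mean_matching_r2 = mean(d$matching_r2),
                     sd_matching_r2 = sd(d$matching_r2),
                     mean_structure_r2 = mean(d$structure_r2),
                     sd_structure_r2 = sd(d$structure_r2),
                     mean_no_cue_response = mean(d$no_cue_response),
                     sd_no_cue_response = sd(d$no_cue_response))
    }))
  rownames(summary) <- NULL
  structure(list(networks = networks, sets = sets,
                 summary = tibble::as_tibble(summary), label = label),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %s (%d networks, %d training sets)\n",
              x$label, nrow(x$networks), nrow(x$sets)))
  print(x$summary)
  invisible(x)
}

# Train nets_per_set perceptrons on one training set and measure each one.
run_condition_set <- function(ts, nets_per_set, config, net_seeds,
                              condition, set_id) {
  fit <- fit_logistic(ts)
  observed <- empirical_pattern_frequencies(ts)
  dep <- conditional_dependence(ts)
  valid <- validate_training_set(ts)
  nets <- lapply(seq_len(nets_per_set), function(j) {
    cfg <- config
    cfg$seed <- net_seeds[j]
    trained <- train_perceptron(ts, cfg)
    w <- trained$perceptron$weights
    tibble::tibble(condition = condition, set = set_id, net = j,
                   net_seed = net_seeds[j],
                   matching_r2 = matching_r2(trained$responses, observed),
                   structure_r2 = structure_fit_r2(trained, fit),
                   no_cue_response = unname(trained$responses[1]),
                   bias = trained$perceptron$bias,
                   w_a = w[["a"]], w_b = w[["b"]],
                   w_x = w[["x"]], w_y = w[["y"]],
                   dependence_total = dep$total)
  })
  set_row <- tibble::tibble(condition = condition, set = set_id,
                            set_seed = ts$seed,
                            chi2_rewarded = dep$chi2_rewarded,
                            chi2_unrewarded = dep$chi2_unrewarded,
                            dependence_total = dep$total,
                            n_configs_pass = sum(valid$pass),
                            logistic_converged = fit$converged)
  list(networks = do.call(rbind, nets), set = set_row)
}

#' Run the independent-cue probability-matching experiment
#'
#' Generates `sets` training sets from the independent-cue preset (A 0.2,
#' B 0.4, X 0.6, Y 0.8; optional no-cue baseline), validates each, trains
#' `nets_per_set` perceptrons per set with distinct derived seeds, and
#' records each network's probability-matching fit (squared correlation of
#' its 16 responses with the set's observed reward rates), its
#' structure-vs-regression-coefficients fit, and its response to the
#' all-absent pattern.
#'
#' @param sets Number of training sets (default 5).
#' @param nets_per_set Perceptrons trained per set (default 20).
#' @param baseline_prob No-cue reward probability of the generating model
#'   (default 0; 0.05 and 0.10 are the studied variants).
#' @param config A [training_config()]; its `seed` is ignored — per-network
#'   seeds are derived from `master_seed`.
#' @param master_seed Integer seed from which all set and network seeds
#'   are derived; identical `master_seed` reproduces every number exactly.
#' @param replicates Trials per configuration in each set (default 100).
#' @return An `"experiment_result"`: tibbles `networks` (one row per
#'   trained perceptron), `sets` (one row per training set), `summary`
#'   (means and SDs), and a `label`.
#' @export
run_simulation1 <- function(sets = 5, nets_per_set = 20, baseline_prob = 0,
                            config = training_config(), master_seed = 1,
                            replicates = 100) {
  stopifnot(sets >= 1, nets_per_set >= 1)
  model <- sim1_model(baseline_prob)
  seeds <- matrix(derive_seeds(master_seed, sets * (nets_per_set + 1L)),
                  nrow = sets)
  condition <- sprintf("independent/baseline=%.2g", baseline_prob)
  pieces <- lapply(seq_len(sets), function(i) {
    ts <- generate_training_set(model, replicates, seeds[i, 1])
    run_condition_set(ts, nets_per_set, config, seeds[i, -1],
                      condition, i)
  })
  new_experiment_result(do.call(rbind, lapply(pieces, `[[`, "networks")),
                        do.call(rbind, lapply(pieces, `[[`, "set")),
                        label = condition)
}

#' Run the cue-interaction (conditional-dependence) experiment
#'
#' The 2x2 factorial: gate kind (AND vs XOR on cues X, Y) crossed with
#' gate reward probability (0.6 vs 0.1), with A 0.2 and B 0.4 independent
#' and no-cue baseline 0. Generates `sets_per_condition` training sets per
#' cell, trains `nets_per_set` perceptrons on each, and records matching
#' fit and each set's conditional-dependence score.
#'
#' @inheritParams run_simulation1
#' @param sets_per_condition Training sets per factorial cell (default 5).
#' @param gate_probs The two gate reward probabilities (default
#'   `c(0.6, 0.1)`).
#' @return An `"experiment_result"` whose `networks` tibble carries
#'   `gate_kind` and `gate_prob` factor columns for the factorial
#'   analyses.
#' @export
run_simulation2 <- function(sets_per_condition = 5, nets_per_set = 20,
                            config = training_config(), master_seed = 1,
                            replicates = 100, gate_probs = c(0.6, 0.1)) {
  stopifnot(sets_per_condition >= 1, nets_per_set >= 1)
  grid <- expand.grid(gate_prob = gate_probs, kind = c("and", "xor"),
                      stringsAsFactors = FALSE)
  seeds <- matrix(derive_seeds(master_seed,
                               nrow(grid) * sets_per_condition *
                                 (nets_per_set + 1L)),
                  nrow = nrow(grid) * sets_per_condition)
  pieces <- lapply(seq_len(nrow(grid)), function(g) {
    model <- sim2_model(grid$kind[g], grid$gate_prob[g])
    condition <- sprintf("%s/%.2g", grid$kind[g], grid$gate_prob[g])
    lapply(seq_len(sets_per_condition), function(i) {
      row <- (g - 1L) * sets_per_condition + i
      ts <- generate_training_set(model, replicates, seeds[row, 1])
      piece <- run_condition_set(ts, nets_per_set, config, seeds[row, -1],
                                 condition, i)
      piece$networks$gate_kind <- grid$kind[g]
      piece$networks$gate_prob <- grid$gate_prob[g]
      piece$set$gate_kind <- grid$kind[g]
      piece$set$gate_prob <- grid$gate_prob[g]
      piece
    })
  })
  pieces <- unlist(pieces, recursive = FALSE)
  new_experiment_result(do.call(rbind, lapply(pieces, `[[`, "networks")),
                        do.call(rbind, lapply(pieces, `[[`, "set")),
                        label = "gate factorial (AND/XOR x 0.6/0.1)")
}

#' Balanced two-way fixed-effects ANOVA from cell sums of squares
#'
#' Partitions the total sum of squares of a response measured under a
#' balanced 2x2 design into the two main effects, their interaction, and
#' error, and forms the F ratios with df `(1, N - 4)`. Computed directly
#' from cell and marginal means; requires equal cell counts.
#'
#' @param data A data frame with the response and two factor columns.
#' @param response,factor_a,factor_b Column names (defaults match the
#'   `networks` tibble of [run_simulation2()]).
#' @return A tibble with one row per term (`factor_a`, `factor_b`,
#'   `interaction`): `df1`, `df2`, `ss`, `F`, `p`.
#' @export
two_way_anova <- function(data, response = "matching_r2",
                          factor_a = "gate_kind", factor_b = "gate_prob") {
  y <- data[[response]]
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  stopifnot(nlevels(fa) == 2L, nlevels(fb) == 2L)
  counts <- table(fa, fb)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("two_way_anova requires a balanced design (equal cell counts)",
         call. = FALSE)
  }
  n_cell <- counts[1, 1]
  N <- length(y)
  grand <- mean(y)
  mean_a <- tapply(y, fa, mean)
  mean_b <- tapply(y, fb, mean)
  mean_ab <- tapply(y, list(fa, fb), mean)
  ss_a <- 2L * n_cell * sum((mean_a - grand)^2)
  ss_b <- 2L * n_cell * sum((mean_b - grand)^2)
  ss_cells <- n_cell * sum((mean_ab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - mean_ab[cbind(as.integer(fa), as.integer(fb))])^2)
  df2 <- N - 4L
  ms_err <- ss_err / df2
  ss <- c(ss_a, ss_b, ss_ab)
  Fv <- ss / ms_err
  tibble::tibble(term = c(factor_a, factor_b, "interaction"),
                 df1 = 1L, df2 = df2, ss = ss, F = Fv,
                 p = pf(Fv, 1, df2, lower.tail = FALSE))
}

#' Simple linear regression summary for predicting matching fit
#'
#' Ordinary least-squares regression of a response on a single predictor
#' (either the continuous conditional-dependence score of each network's
#' training set, or the AND/XOR dichotomy coded 0/1), reported as the
#' squared correlation together with its F test,
#' \eqn{F = (N - 2) R^2 / (1 - R^2)} on df `(1, N - 2)`.
#'
#' @param response Numeric response vector (one value per network).
#' @param predictor Numeric predictor of the same length.
#' @return A list with `r_squared`, `F`, `df1`, `df2`, `p`, `slope`,
#'   `intercept`.
#' @export
regress_fit <- function(response, predictor) {
  stopifnot(length(response) == length(predictor), length(response) >= 3)
  if (sd(predictor) == 0) {
    stop("regress_fit is undefined for a zero-variance predictor",
         call. = FALSE)
  }
  N <- length(response)
  r2 <- cor(response, predictor)^2
  slope <- cor(response, predictor) * sd(response) / sd(predictor)
  Fv <- (N - 2) * r2 / (1 - r2)
  list(r_squared = r2, F = Fv, df1 = 1L, df2 = N - 2L,
       p = pf(Fv, 1, N - 2, lower.tail = FALSE),
       slope = slope, intercept = mean(response) - slope * mean(predictor))
}

#' Write experiment results as tidy CSV files plus a JSON manifest
#'
#' @param result An `"experiment_result"`.
#' @param dir Output directory (created if needed); writes
#'   `networks.csv`, `sets.csv`, `summary.csv` and `manifest.json`.
#' @return The directory path, invisibly.
#' @export
write_experiment_result <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$networks, file.path(dir, "networks.csv"),
            row.names = FALSE)
  write.csv(result$sets, file.path(dir, "sets.csv"), row.names = FALSE)
  write.csv(result$summary, file.path(dir, "summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(label = result$label, n_networks = nrow(result$networks),
         n_sets = nrow(result$sets),
         files = c("networks.csv", "sets.csv", "summary.csv"),
         written = format(Sys.time(), tz = "UTC")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
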