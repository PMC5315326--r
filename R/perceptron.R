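#' A single logistic output unit over the four cues
#'
#' The perceptron holds one connection weight per cue plus a bias
#' \eqn{\theta}; its response to a stimulus is
#' \eqn{a = 1 / (1 + e^{-(\sum_i w_i x_i + \theta)})}. Weights and bias
#' live on the log-odds scale, which is what ties a trained unit to the
#' coefficients of a logistic regression.
#'
#' @param weights Named numeric vector of four finite weights
#'   (`a`, `b`, `x`, `y`).
#' @param bias Finite numeric bias of the activation function.
#' @return An object of class `"perceptron"`.
#' @examples
#' p <- perceptron(c(a = 1, b = -1, x = 0, y = 0), bias = 0)
#' activate(p, c(1, 1, 0, 0))  # 0.5: the two weights cancel
#' @export
perceptron <- function(weights = c(a = 0, b = 0, x = 0, y = 0), bias = 0) {
  weights <- unlist(weights)
  if (is.null(names(weights))) names(weights) <- cue_names()
  stopifnot(length(weights) == 4L, all(is.finite(weights)),
            identical(sort(names(weights)), sort(cue_names())),
            length(bias) == 1L, is.finite(bias))
  structure(list(weights = weights[cue_names()], bias = as.numeric(bias)),
            class = "perceptron")
}

#' @export
print.perceptron <- function(x, ...) {
  cat("Logistic perceptron (log-odds scale)\n")
  cat("  weights:", paste(sprintf("%s=%.4f", toupper(names(x$weights)),
                                  x$weights), collapse = ", "), "\n")
  cat(sprintf("  bias:    %.4f\n", x$bias))
  invisible(x)
}

#' Response of a perceptron to a cue pattern
#'
#' Computes the logistic activation of the net input, using an
#' overflow-safe evaluation so extreme net inputs saturate smoothly
#' instead of producing `NaN`.
#'
#' @param p A [perceptron()].
#' @param pattern A length-4 0/1 vector `(a, b, x, y)`.
#' @return Activity in `(0, 1)` (up to floating-point saturation).
#' @export
activate <- function(p, pattern) {
  stopifnot(inherits(p, "perceptron"))
  xp <- as_cue_pattern(pattern)
  plogis(sum(p$weights * xp) + p$bias)
}

#' Responses to all sixteen cue configurations
#'
#' @param p A [perceptron()].
#' @return Numeric vector of 16 activities in enumeration order, named by
#'   pattern label.
#' @export
respond_all <- function(p) {
  stopifnot(inherits(p, "perceptron"))
  pats <- cue_patterns()
  out <- plogis(as.vector(pats %*% p$weights) + p$bias)
  names(out) <- rownames(pats)
  out
}

#' Training hyperparameters for the delta-rule trainer
#'
#' @param learning_rate Step size \eqn{\eta} (default 0.05).
#' @param epochs Number of passes through the training set (default 2500).
#' @param init_half_range Initial weights are drawn uniformly from
#'   `[-init_half_range, init_half_range]` (default 0.1); the bias starts
#'   at 0.
#' @param loss `"cross_entropy"` (default) uses the exact gradient of the
#'   Bernoulli log-likelihood, error signal \eqn{\delta = t - a}; this is
#'   the choice under which per-pattern gradient descent converges to the
#'   logistic-regression maximum likelihood solution. `"squared_error"`
#'   uses \eqn{\delta = (t - a)\,a\,(1 - a)} and is provided for
#'   comparison.
#' @param seed Integer seed; the weight-initialization stream and the
#'   per-epoch shuffling stream are derived from it independently, so
#'   either can be held fixed while the other varies.
#' @param record_epochs Epochs after which the 16 responses are stored in
#'   the trajectory. The default mirrors the early-dense schedule used to
#'   watch learning unfold: 1, 5, 10, 15, 20, 25, 50, 75, 100, then every
#'   100 epochs.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(learning_rate = 0.05, epochs = 2500,
                            init_half_range = 0.1,
                            loss = c("cross_entropy", "squared_error"),
                            seed = 1L,
                            record_epochs = default_record_epochs(epochs)) {
  loss <- match.arg(loss)
  stopifnot(learning_rate >= 0, epochs >= 1, init_half_range >= 0)
  record_epochs <- sort(unique(as.integer(record_epochs)))
  stopifnot(all(record_epochs >= 1), all(record_epochs <= epochs))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 init_half_range = init_half_range, loss = loss,
                 seed = as.integer(seed), record_epochs = record_epochs),
            class = "training_config")
}

#' @rdname training_config
#' @export
default_record_epochs <- function(epochs) {
  epochs <- as.integer(epochs)
  e <- c(1L, 5L, 10L, 15L, 20L, 25L, 50L, 75L, 100L,
         if (epochs >= 200L) seq(200L, epochs, by = 100L))
  sort(unique(c(e[e <= epochs], epochs)))
}

#' One delta-rule update after a single pattern presentation
#'
#' Reference (R-level) form of the per-pattern update applied by
#' [train_perceptron()]: with activity `a`, the error signal is
#' \eqn{\delta = t - a} for cross-entropy or
#' \eqn{\delta = (t - a) a (1 - a)} for squared error, and
#' \eqn{w_i \leftarrow w_i + \eta\,\delta\,x_i},
#' \eqn{\theta \leftarrow \theta + \eta\,\delta}. Weights of absent cues
#' are untouched.
#'
#' @param p A [perceptron()].
#' @param pattern A length-4 0/1 cue vector.
#' @param target Reward target; 0 or 1 during training, though any value
#'   in `[0, 1]` is accepted so the rule's fixed point can be examined.
#' @param config A [training_config()] (supplies `learning_rate`, `loss`).
#' @return The updated `"perceptron"`.
#' @export
update_step <- function(p, pattern, target, config) {
  stopifnot(inherits(p, "perceptron"), target >= 0, target <= 1)
  xp <- as_cue_pattern(pattern)
  a <- activate(p, pattern)
  delta <- (target - a)
  if (config$loss == "squared_error") delta <- delta * a * (1 - a)
  perceptron(p$weights + config$learning_rate * delta * xp,
             p$bias + config$learning_rate * delta)
}

# Two sub-seeds below 2^31 from one training seed: one for weight init,
# one for the per-epoch shuffling stream.
derive_streams <- function(seed) {
  m <- .Machine$integer.max
  init <- (as.integer(seed) %% m)
  perm <- ((as.integer(seed) + 1013904223) %% m)
  c(init = init, perm = perm)
}

#' Train a perceptron on a training set by per-pattern gradient descent
#'
#' Initializes the four weights uniformly in
#' `[-init_half_range, init_half_range]` and the bias at 0, then for each
#' epoch presents every row of the training set in a fresh uniform random
#' permutation, applying the per-pattern delta-rule update of
#' [update_step()] after each presentation (stochastic training, not
#' batch). After each epoch listed in `config$record_epochs` the responses
#' to all 16 configurations are stored. The inner loop is compiled code;
#' it aborts with the epoch and row index should the weights ever become
#' non-finite.
#'
#' @param ts A [generate_training_set()] result (or any `"training_set"`).
#' @param config A [training_config()].
#' @return A list of class `"trained_perceptron"` with elements
#'   `perceptron` (final state), `trajectory` (tibble: `epoch` plus one
#'   response column per pattern label), `responses` (final 16 responses),
#'   and `config`.
#' @examples
#' ts <- generate_training_set(sim1_model(), replicates = 10, seed = 1)
#' fit <- train_perceptron(ts, training_config(epochs = 50, seed = 2))
#' round(fit$responses, 2)
#' @export
train_perceptron <- function(ts, config = training_config()) {
  stopifnot(inherits(ts, "training_set"), nrow(ts$rows) > 0,
            inherits(config, "training_config"))
  streams <- derive_streams(config$seed)
  w0 <- withr::with_seed(streams[["init"]],
                         runif(4, -config$init_half_range,
                               config$init_half_range))
  pats <- cue_patterns()
  idx <- as.integer(8L * ts$rows$a + 4L * ts$rows$b +
                      2L * ts$rows$x + ts$rows$y)
  res <- withr::with_seed(streams[["perm"]], {
    .train_sgd(idx, `storage.mode<-`(pats, "double"),
               as.integer(ts$rows$target), w0, 0,
               config$learning_rate, config$epochs,
               config$loss == "cross_entropy", config$record_epochs)
  })
  final <- perceptron(`names<-`(res$weights, cue_names()), res$bias)
  traj <- tibble::as_tibble(as.data.frame(res$trajectory))
  names(traj) <- pattern_labels()
  traj <- tibble::add_column(traj, epoch = config$record_epochs,
                             .before = 1)
  structure(list(perceptron = final, trajectory = traj,
                 responses = respond_all(final), config = config),
            class = "trained_perceptron")
}

#' @export
print.trained_perceptron <- function(x, ...) {
  cat(sprintf("Trained perceptron (%s, eta=%g, %d epochs)\n",
              x$config$loss, x$config$learning_rate, x$config$epochs))
  print(x$perceptron)
  invisible(x)
}

#' Serialize a perceptron to JSON and back
#'
#' @param p A [perceptron()].
#' @param path JSON file path.
#' @return `write_perceptron` returns `path` invisibly; `read_perceptron`
#'   the reconstructed `"perceptron"`.
#' @export
write_perceptron <- function(p, path) {
  stopifnot(inherits(p, "perceptron"))
  jsonlite::write_json(list(weights = as.list(p$weights), bias = p$bias),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perceptron
#' @export
read_perceptron <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  perceptron(unlist(obj$weights), obj$bias)
}
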