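#' Observed reward rate of each cue configuration in a training set
#'
#' @param ts A `"training_set"`.
#' @return Numeric vector of 16 observed rates (rewarded trials divided by
#'   trials) in enumeration order, named by pattern label. Errors if any
#'   configuration is absent from the set.
#' @export
empirical_pattern_frequencies <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  idx <- 8L * ts$rows$a + 4L * ts$rows$b + 2L * ts$rows$x + ts$rows$y
  n <- tabulate(idx + 1L, nbins = 16L)
  if (any(n == 0L)) {
    stop("configuration(s) absent from the training set: ",
         paste(pattern_labels()[n == 0L], collapse = ", "), call. = FALSE)
  }
  k <- vapply(0:15, function(i) sum(ts$rows$target[idx == i]), numeric(1))
  out <- k / n
  names(out) <- pattern_labels()
  out
}

#' Probability-matching fit between responses and reward rates
#'
#' The squared Pearson correlation between a network's responses to the
#' sixteen configurations and the observed reward rates of those
#' configurations in its training set. By construction it is symmetric in
#' its arguments and invariant to affine rescaling of either one. Note the
#' choice of squared correlation (not \eqn{1 - SSE/SST}): a network can
#' score highly while being uniformly offset.
#'
#' @param responses Numeric vector of 16 activities.
#' @param actual Numeric vector of 16 observed reward rates.
#' @return Squared correlation in `[0, 1]`. Errors if either vector has
#'   zero variance.
#' @examples
#' matching_r2(c(0.1, 0.5, 0.9), c(0.15, 0.55, 0.8) )
#' @export
matching_r2 <- function(responses, actual) {
  stopifnot(length(responses) == length(actual), length(actual) >= 3)
  if (sd(responses) == 0 || sd(actual) == 0) {
    stop("matching_r2 is undefined when either vector has zero variance",
         call. = FALSE)
  }
  cor(responses, actual)^2
}

#' Maximum-likelihood logistic regression of reward on the four cues
#'
#' Fits the main-effects-only model
#' \eqn{\mathrm{logit}\,P(R = 1 \mid a,b,x,y) =
#' \beta_0 + \beta_1 a + \beta_2 b + \beta_3 x + \beta_4 y}
#' (no interaction terms) by iteratively reweighted least squares, on the
#' per-configuration grouped binomial counts — likelihood-identical, up to
#' a constant, to fitting the individual Bernoulli rows, and much faster.
#' Quasi-separation (coefficients running away because some configuration
#' is perfectly predicted) is detected and flagged rather than left to
#' iterate.
#'
#' @param ts A `"training_set"` in which both target values occur.
#' @return A list of class `"logistic_fit"`: `coefficients` (named
#'   `intercept, a, b, x, y`, log-odds units), `log_likelihood` (grouped
#'   binomial scale), `converged`, `iterations`, `separation`.
#' @export
fit_logistic <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  if (length(unique(ts$rows$target)) < 2L) {
    stop("degenerate training set: only one target value present",
         call. = FALSE)
  }
  idx <- 8L * ts$rows$a + 4L * ts$rows$b + 2L * ts$rows$x + ts$rows$y
  n <- tabulate(idx + 1L, nbins = 16L)
  k <- vapply(0:15, function(i) sum(ts$rows$target[idx == i]), numeric(1))
  dat <- as.data.frame(cue_patterns())
  present <- n > 0
  fit <- glm(cbind(k[present], n[present] - k[present]) ~ a + b + x + y,
             data = dat[present, , drop = FALSE], family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  co <- coef(fit)
  names(co) <- c("intercept", cue_names())
  separation <- any(abs(co) > 15, na.rm = TRUE)  # co has NAs if aliased
  if (separation) {
    warning("coefficients suggest quasi-separation; estimates unreliable",
            call. = FALSE)
  }
  structure(list(coefficients = co,
                 log_likelihood = as.numeric(logLik(fit)),
                 converged = fit$converged && !separation,
                 iterations = fit$iter,
                 separation = separation),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Main-effects logistic regression (log-odds coefficients)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.3f, %sconverged in %d iterations\n",
              x$log_likelihood, if (x$converged) "" else "NOT ",
              x$iterations))
  invisible(x)
}

#' Agreement between perceptron structure and regression coefficients
#'
#' Squared Pearson correlation over the five paired values: bias vs
#' intercept and each cue's connection weight vs its main-effect slope.
#' A trained perceptron whose structure implements the logistic regression
#' of its own training set scores near 1.
#'
#' @param p A [perceptron()] (or a `"trained_perceptron"`).
#' @param fit A converged [fit_logistic()] result.
#' @return Squared correlation in `[0, 1]`.
#' @export
structure_fit_r2 <- function(p, fit) {
  if (inherits(p, "trained_perceptron")) p <- p$perceptron
  stopifnot(inherits(p, "perceptron"), inherits(fit, "logistic_fit"))
  matching_r2(c(p$bias, p$weights), unname(fit$coefficients))
}

#' Interpret a connection weight as an odds ratio
#'
#' A trained weight lives on the log-odds scale, so `exp(weight)` is the
#' multiplicative change in reward odds attributable to the cue's
#' presence, the other cues held constant.
#'
#' @param weight Finite numeric weight(s).
#' @return `exp(weight)`.
#' @examples
#' weight_to_odds_ratio(log(4))  # 4
#' @export
weight_to_odds_ratio <- function(weight) {
  stopifnot(is.numeric(weight), all(is.finite(weight)))
  exp(weight)
}

# Uncorrected Pearson chi-square of independence on a 2x2 count table;
# a zero row or column margin (or an empty table) yields 0 by convention.
pearson_chi2_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  N <- sum(tab)
  r <- rowSums(tab)
  cl <- colSums(tab)
  if (N == 0 || any(r == 0) || any(cl == 0)) return(0)
  E <- outer(r, cl) / N
  sum((tab - E)^2 / E)
}

#' Reward-stratified chi-square measure of conditional dependence
#'
#' Operationalizes the degree of conditional dependence between a pair of
#' cues: split the trials by reward outcome, build in each stratum the
#' 2x2 table of presence/absence of the two cues (collapsing over the
#' other cues), compute the uncorrected Pearson chi-square of independence
#' on each table, and sum the two statistics. Under conditional
#' independence of the pair given reward the sum stays near its null
#' level; an interaction gate on the pair inflates it. A stratum with a
#' zero margin (or no trials) contributes 0.
#'
#' @param ts A `"training_set"`.
#' @param cues Character pair of cue names (default `c("x", "y")`).
#' @return A list of class `"dependence_score"` with `chi2_rewarded`,
#'   `chi2_unrewarded` and their sum `total`.
#' @export
conditional_dependence <- function(ts, cues = c("x", "y")) {
  stopifnot(inherits(ts, "training_set"), nrow(ts$rows) > 0,
            length(cues) == 2L, all(cues %in% cue_names()))
  u <- ts$rows[[cues[1]]]
  v <- ts$rows[[cues[2]]]
  strat_chi2 <- function(sel) {
    tab <- matrix(c(sum(sel & u == 0 & v == 0), sum(sel & u == 0 & v == 1),
                    sum(sel & u == 1 & v == 0), sum(sel & u == 1 & v == 1)),
                  nrow = 2L, byrow = TRUE)
    pearson_chi2_2x2(tab)
  }
  rew <- strat_chi2(ts$rows$target == 1L)
  unrew <- strat_chi2(ts$rows$target == 0L)
  structure(list(chi2_rewarded = rew, chi2_unrewarded = unrew,
                 total = rew + unrew),
            class = "dependence_score")
}

#' @export
print.dependence_score <- function(x, ...) {
  cat(sprintf(
    "Conditional dependence: chi2 rewarded %.2f + unrewarded %.2f = %.2f\n",
    x$chi2_rewarded, x$chi2_unrewarded, x$total))
  invisible(x)
}
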