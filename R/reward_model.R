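#' Define a population reward structure over four binary cues
#'
#' A reward model attaches an independent Bernoulli reward lottery to each
#' listed cue, optionally replaces the lotteries of a pair of cues with a
#' single lottery gated by a logical condition (AND or XOR) on that pair,
#' and may grant a baseline lottery on the all-absent configuration. On a
#' given stimulus each active lottery fires independently, and the trial is
#' rewarded (once) if any of them fires, so reward sources combine by the
#' addition rule for independent probabilities,
#' \eqn{P = 1 - \prod_s (1 - p_s)}.
#'
#' @param independent_probs Named numeric vector of per-cue reward
#'   probabilities in `[0, 1]`; names must be among `"a","b","x","y"`.
#'   Cues taking part in `gate` must not appear here.
#' @param gate `NULL`, or a list with elements `kind` (`"and"` or `"xor"`),
#'   `prob` (reward probability in `[0, 1]` paid when the logical condition
#'   holds) and optionally `cues` (character pair, default `c("x","y")`).
#'   Gated cues carry no independent lottery of their own: only the gate
#'   pays.
#' @param baseline_prob Reward probability in `[0, 1]` applied only when
#'   all four cues are absent (it is not a background lottery on every
#'   trial).
#' @return An object of class `"reward_model"`.
#' @seealso [sim1_model()], [sim2_model()], [expected_reward_probability()]
#' @examples
#' sim1_model()
#' sim2_model("xor", 0.6)
#' @export
reward_model <- function(independent_probs = numeric(),
                         gate = NULL,
                         baseline_prob = 0) {
  independent_probs <- unlist(independent_probs)
  if (length(independent_probs) > 0) {
    if (is.null(names(independent_probs)) ||
        !all(names(independent_probs) %in% cue_names())) {
      stop("independent_probs must be named with cues among 'a','b','x','y'",
           call. = FALSE)
    }
    check_prob(independent_probs, "independent_probs")
  }
  if (!is.null(gate)) {
    if (!is.list(gate) || is.null(gate$kind) || is.null(gate$prob)) {
      stop("gate must be a list with elements kind and prob", call. = FALSE)
    }
    gate$kind <- match.arg(tolower(gate$kind), c("and", "xor"))
    if (is.null(gate$cues)) gate$cues <- c("x", "y")
    gate$cues <- tolower(gate$cues)
    if (length(gate$cues) != 2L || !all(gate$cues %in% cue_names()) ||
        gate$cues[1] == gate$cues[2]) {
      stop("gate$cues must be two distinct cues among 'a','b','x','y'",
           call. = FALSE)
    }
    check_prob(gate$prob, "gate$prob")
    if (any(gate$cues %in% names(independent_probs))) {
      stop("a cue cannot both carry an independent lottery and take part ",
           "in the gate", call. = FALSE)
    }
    gate <- gate[c("kind", "cues", "prob")]
  }
  check_prob(baseline_prob, "baseline_prob")
  structure(
    list(independent_probs = independent_probs, gate = gate,
         baseline_prob = as.numeric(baseline_prob)),
    class = "reward_model"
  )
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.reward_model <- function(x, ...) {
  cat("Reward model over cues A, B, X, Y\n")
  if (length(x$independent_probs)) {
    cat("  independent lotteries:",
        paste(sprintf("%s=%.3g", toupper(names(x$independent_probs)),
                      x$independent_probs), collapse = ", "), "\n")
  }
  if (!is.null(x$gate)) {
    cat(sprintf("  gate: %s(%s) pays %.3g\n", toupper(x$gate$kind),
                paste(toupper(x$gate$cues), collapse = ","), x$gate$prob))
  }
  cat(sprintf("  no-cue baseline: %.3g\n", x$baseline_prob))
  invisible(x)
}

#' Preset reward model with four independent cues
#'
#' Cues A, B, X and Y independently signal reward probabilities 0.20,
#' 0.40, 0.60 and 0.80; no interaction gate.
#'
#' @param baseline_prob Reward probability on the all-absent pattern
#'   (default 0; the variants 0.05 and 0.10 probe how a nonzero no-cue
#'   rate improves matching of that pattern).
#' @return A `"reward_model"`.
#' @export
sim1_model <- function(baseline_prob = 0) {
  reward_model(independent_probs = c(a = 0.20, b = 0.40, x = 0.60, y = 0.80),
               baseline_prob = baseline_prob)
}

#' Preset reward model with an interaction gate on cues X and Y
#'
#' Cues A (0.2) and B (0.4) stay independent; X and Y carry no lotteries of
#' their own and instead a logical gate on the pair pays `gate_prob` when
#' its condition holds (`"and"`: both present; `"xor"`: exactly one
#' present). The no-cue baseline is 0. The XOR variant makes the reward
#' structure linearly nonseparable.
#'
#' @param kind `"and"` or `"xor"`.
#' @param gate_prob Gate reward probability (the study uses 0.6 and 0.1).
#' @return A `"reward_model"`.
#' @export
sim2_model <- function(kind = c("and", "xor"), gate_prob = 0.6) {
  kind <- match.arg(kind)
  reward_model(independent_probs = c(a = 0.20, b = 0.40),
               gate = list(kind = kind, cues = c("x", "y"), prob = gate_prob))
}

# Probabilities of the reward sources active on one pattern, in the fixed
# draw order A, B, X-or-gate, Y (baseline only on the all-absent pattern).
reward_sources <- function(model, pattern) {
  p <- as_cue_pattern(pattern)
  src <- numeric(0)
  for (cue in cue_names()) {
    if (p[[cue]] == 1L && cue %in% names(model$independent_probs)) {
      src <- c(src, model$independent_probs[[cue]])
    }
    if (cue == "x" && !is.null(model$gate)) {
      g <- model$gate
      on <- p[[g$cues[1]]] == 1L
      on2 <- p[[g$cues[2]]] == 1L
      fires <- if (g$kind == "and") on && on2 else xor(on, on2)
      if (fires) src <- c(src, g$prob)
    }
  }
  if (all(p == 0L) && model$baseline_prob > 0) {
    src <- c(src, model$baseline_prob)
  }
  src
}

#' Expected reward probability of a cue pattern under a reward model
#'
#' Active reward sources fire independently, so the expected probability is
#' the union \eqn{1 - \prod_s (1 - p_s)} over the sources active on the
#' pattern: each present cue with an independent lottery, the gate when its
#' logical condition on the pair holds, and the baseline on the all-absent
#' pattern. For two sources this reduces to the familiar addition rule
#' \eqn{p_1 + p_2 - p_1 p_2}.
#'
#' @param model A [reward_model()].
#' @param pattern A length-4 0/1 vector `(a, b, x, y)`, or a 16-row matrix
#'   of patterns as from [cue_patterns()].
#' @return A probability in `[0, 1]`, or a vector of them for a matrix
#'   input (in enumeration order, named by pattern label).
#' @examples
#' expected_reward_probability(sim1_model(), c(1, 1, 0, 0))  # 0.52
#' expected_reward_probability(sim2_model("xor", 0.6), c(0, 0, 1, 1))  # 0
#' @export
expected_reward_probability <- function(model, pattern = cue_patterns()) {
  stopifnot(inherits(model, "reward_model"))
  if (is.matrix(pattern)) {
    out <- apply(pattern, 1L, function(r) {
      1 - prod(1 - reward_sources(model, r))
    })
    names(out) <- rownames(pattern)
    return(out)
  }
  1 - prod(1 - reward_sources(model, pattern))
}
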