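---
title: "Probability matching in logistic perceptrons: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability matching in logistic perceptrons: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuematch)
```

`cuematch` is built around one phenomenon from the animal-learning end of
computational neuroscience: a single logistic output unit, trained
trial-by-trial on stochastically rewarded cue configurations, comes to
*match probability* — its activity to a stimulus converges on the
historical reward rate of that stimulus rather than on a hard
classification. This vignette is the package's own account of the model,
the synthetic reward worlds it is trained in, the statistics used to
measure it, and the design decisions taken where more than one reasonable
convention exists.

## 1. The reward world

A `reward_model()` describes a population of trials over four binary cues
A, B, X, Y. Three kinds of reward source exist:

* an **independent lottery** per cue: when the cue is present, reward is
  granted with its probability (preset `sim1_model()`: A = 0.20,
  B = 0.40, X = 0.60, Y = 0.80);
* an optional **gate** on the pair (X, Y): the pair's own lotteries are
  removed and a single lottery with probability `gate_prob` fires only
  when the logical condition holds (`and`: both present; `xor`: exactly
  one present) — presets `sim2_model(kind, gate_prob)` with A = 0.2 and
  B = 0.4 kept independent;
* a **baseline** lottery applied *only* to the all-absent configuration.

A trial is rewarded at most once, whichever sources fire, so the expected
reward probability of a configuration is the union over its active
sources,

$$P(R\mid x) = 1 - \prod_{s \in \text{active}(x)} (1 - p_s),$$

which for two sources is the addition rule
$p_1 + p_2 - p_1 p_2$. `expected_reward_probability()` implements the
product form; tests verify it against the inclusion–exclusion expansion
on two- and three-source cases and check monotonicity in every source
probability.

Two readings of the description above were genuinely open and are fixed
here as design choices. First, the baseline is *conditional on no cues
being present*, not a background lottery added to every trial; a
background lottery would lift all sixteen probabilities and change the
fitted intercept's meaning. Second, gated cues carry no residual
independent lottery — only the gate pays — which is what makes the
gate-probability manipulation a clean dial on the amount of conditional
dependence while holding the logical form fixed.

### Sampling and validation

`generate_training_set()` draws `replicates` trials (default 100) for
each of the sixteen configurations: one uniform number per active source,
consumed in the fixed order A, B, X-or-gate, Y, from a single RNG stream
seeded explicitly. Rows are emitted in enumeration order (binary counting,
A most significant); randomizing *presentation* order is deliberately the
trainer's job, so that the same sampled set can be re-trained under
different shuffling seeds, and identical `(model, replicates, seed)`
reproduce the set bit for bit.

`validate_training_set()` compares each configuration's observed
(reward, no-reward) counts with the model's expected counts by a 1-df
Pearson goodness-of-fit statistic, uncorrected. Conventions: a cell with
expected count zero contributes nothing (it can only arise when the
expected probability is exactly 0 or 1, where the configuration instead
passes iff its observed counts are equally degenerate). With sixteen
tests per set at $\alpha = 0.05$, roughly one nominal failure per set is
expected by chance; the default is therefore report-only, and
`generate_valid_training_set()` offers an explicit accept/reject loop
(successive seeds, at most 20 draws) for workflows that want every
configuration to pass.

### What the generator emulates — and what it does not

The generator reproduces the *statistical* structure of a cue-combination
reinforcement experiment: simultaneous binary cues, independent or gated
reward lotteries, a fixed number of trials per configuration. Trials are
exchangeable within a configuration; there is no session structure, no
sequential dependence, no drift in reward probabilities, no continuous
cue intensity, and no subject-level variability. Passing tests therefore
show that the learning rule behaves as analysed under i.i.d. stationary
contingencies; they do not show robustness to the nonstationarity or
autocorrelation of real behavioural data.

## 2. The learner

`perceptron()` holds four connection weights and a bias $\theta$, all on
the log-odds scale. The response to configuration $x$ is the logistic
activation

$$a = \frac{1}{1 + e^{-(\sum_i w_i x_i + \theta)}},$$

evaluated in a two-branch overflow-safe form (the naive expression
overflows for $|net| \gtrsim 700$).

`train_perceptron()` initializes weights uniformly in
$[-0.1, 0.1]$ (bias 0), then for each epoch presents all rows in a fresh
uniform permutation and applies the per-pattern update of
`update_step()` after every presentation — stochastic training, never
batch. Two losses are exposed:

* `cross_entropy` (default): error signal $\delta = t - a$, the exact
  gradient of the Bernoulli log-likelihood. This choice is what makes
  trial-level gradient descent converge to the maximum-likelihood
  logistic regression of the data, the package's central correctness
  property (tested as a squared correlation above 0.99 between
  $(\theta, w)$ and the fitted coefficients).
* `squared_error`: $\delta = (t - a)\,a(1 - a)$, provided for comparison
  with trainers built on the squared-error gradient. The published
  description of the original trainer does not pin down its update rule;
  the default here is chosen for the stated mathematical reason, not as
  a claim about that program.

Defaults follow the study conditions: learning rate $\eta = 0.05$
(small enough to approximate the continuous gradient flow, large enough
to converge within a reasonable run) and 2500 epochs. Matching is in
fact established within a few tens of epochs — the test suite asserts
that matching $R^2$ at epoch 50 is within 0.05 of epoch 2500 — which is
why a 250-epoch profile is used for the batch experiments in the test
suite and offered as `--fast` in the analysis scripts, and why the
property also holds for learning rates 0.001 (with more epochs), 0.1 and
0.25.

Reproducibility details: the weight-initialization stream and the
shuffling stream are derived separately from `config$seed`, so either
can be varied in isolation; responses are recorded only *after* an epoch
completes (schedule: epochs 1, 5, 10, 15, 20, 25, 50, 75, 100, then
every 100); and the compiled inner loop aborts with the epoch and row
index if any weight becomes non-finite rather than training on silently.

## 3. Measures

**Matching fit.** `matching_r2()` is the squared Pearson correlation
between the sixteen responses and the sixteen *observed* reward rates of
the network's own training set — observed rather than population rates,
because the network can only be asked to match the contingencies it was
actually shown; population-based $R^2$ can be formed by passing
`expected_reward_probability()` as the second argument. Squared
correlation (not $1 - SSE/SST$) is the deliberate choice: it is
affine-invariant, so a uniformly offset but perfectly ordered response
profile still scores 1, and the no-cue overestimate is surfaced
separately (as the mean response to the all-absent pattern) instead of
being folded into the fit measure.

**Logistic equivalence.** `fit_logistic()` fits the main-effects-only
model (no interaction terms — the whole point of the factorial experiment
is what happens when the model class *cannot* represent the interaction)
by IRLS on the per-configuration grouped binomial counts, which is
likelihood-identical to the 1600 Bernoulli rows up to a constant.
Convergence tolerance is $10^{-10}$ with up to 100 iterations;
quasi-separation is flagged (coefficients beyond ±15 on the logit scale)
rather than iterated on. `structure_fit_r2()` then correlates the five
structural parameters with the five coefficients, and
`weight_to_odds_ratio()` exponentiates a weight into the multiplicative
change in reward odds attributable to a cue.

**Conditional dependence.** `conditional_dependence()` splits trials by
reward outcome, forms the 2×2 presence/absence table of the cue pair in
each stratum (collapsing over the other cues), and sums the two Pearson
χ² statistics of independence. Conventions: no continuity correction
(the correction would systematically shrink the score at these cell
counts), and a stratum with a zero margin or no trials contributes 0 —
that case arises only in degenerate hand-built sets, and the convention
is itself tested. Note that the score is not expected to be at its 1-df
null level even for fully independent lotteries: conditioning on the
reward outcome induces some association among the cues that pay most
often. What matters, and what the factorial experiment exploits, is the
orders-of-magnitude separation between gate conditions.

## 4. The experiments

`run_simulation1()` (independent cues, optional no-cue baseline 0.05 or
0.10) and `run_simulation2()` (the AND/XOR × 0.6/0.1 factorial) generate
sets, train perceptrons, and return tidy per-network, per-set and
summary tables. Seeds derive from one `master_seed` by drawing child
seeds from a master-seeded stream — a simple splitting scheme that
avoids collisions between set seeds and network seeds — and identical
master seeds reproduce every number exactly.

The factorial analyses are computed from first principles, since they
are part of the result rather than plumbing: `two_way_anova()` partitions
sums of squares for the balanced 2×2 design (df 1, 1, 1, N−4) and
`regress_fit()` reports a simple regression as
$R^2$ with $F = (N-2)R^2/(1-R^2)$. Both are cross-checked in the test
suite against `lm()`/`anova()` on simulated data with known structure.
Each network's row in the regressions carries the dependence score of
its *training set* (twenty networks share a set), which is what makes
the regression's N the number of networks.

Problem sizes: the package's full-scale runs use the study conditions
(5 sets × 20 networks per condition, 1600-trial sets, 2500 epochs; the
trial loop is compiled, so a full network trains in under a second). The
test suite runs the same pipelines at 20 networks per experiment arm
with the 250-epoch profile, which the epoch-50 convergence property
shows is statistically equivalent for the quantities being checked.

## 5. Known limitations

* The dependence score's condition means are estimated from small
  numbers of sets in the original design (five per condition); such
  means carry wide sampling bands, and the package's acceptance checks
  use ±2 SD bands accordingly. `scripts/acceptance.R` averages over 20
  sets per condition to stabilise its own estimate.
* Quasi-separated training sets (a configuration with all rewards or
  none, in a direction the main-effects design can chase) produce
  unbounded maximum-likelihood coefficients; the fit flags this rather
  than regularising, because the perceptron-equivalence question is only
  well-posed at an interior optimum.
* The package deliberately stops at one output unit and no hidden
  layers, no momentum or learning-rate schedules, and no interaction
  input units: the scientific question is how a main-effects learner
  behaves when the world violates its independence assumption, not how
  to fix it.

```{r example}
ts <- generate_training_set(sim1_model(), replicates = 100, seed = 42)
net <- train_perceptron(ts, training_config(epochs = 250, seed = 7))
matching_r2(net$responses, empirical_pattern_frequencies(ts))
structure_fit_r2(net, fit_logistic(ts))
```
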