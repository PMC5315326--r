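test_that("empirical frequencies count rewards per configuration", {
  zero <- manual_training_set(rep(0, 16), 10)
  expect_equal(unname(empirical_pattern_frequencies(zero)), rep(0, 16))

  rates <- c(0, 0.63, 0.64, 0.90, 0.35, 0.88, 0.81, 0.98,
             0.21, 0.79, 0.70, 0.96, 0.47, 0.94, 0.77, 0.96)
  ts <- manual_training_set(rates, 100)
  expect_equal(unname(empirical_pattern_frequencies(ts)), rates)

  partial <- partial_training_set(cue_patterns()[1:5, ], rep(0.5, 5))
  expect_error(empirical_pattern_frequencies(partial), "absent")
})

test_that("matching R2 is an affine-invariant, symmetric squared correlation", {
  v <- worked_example()$actual
  expect_equal(matching_r2(v, v), 1)
  expect_equal(matching_r2(0.5 * v + 0.1, v), 1)
  w <- worked_example()$response
  expect_equal(matching_r2(v, w), matching_r2(w, v))
  expect_equal(matching_r2(2 - 3 * v, w), matching_r2(v, w))
  expect_error(matching_r2(rep(0.4, 16), v), "variance")
})

test_that("the published worked-example columns give R2 near 0.97", {
  ex <- worked_example()
  expect_equal(matching_r2(ex$response, ex$actual), 0.97, tolerance = 0.005)
  expect_equal(matching_r2(ex$response, ex$actual), 0.969394,
               tolerance = 1e-5)
})

test_that("logistic fit recovers closed-form logits on saturated designs", {
  # two-cell toy: no-cue rate 0.1, A-only rate 0.6
  toy <- partial_training_set(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0)),
                              c(0.1, 0.6), 100)
  fit <- fit_logistic(toy)
  expect_equal(unname(fit$coefficients["intercept"]), qlogis(0.1),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["a"]), qlogis(0.6) - qlogis(0.1),
               tolerance = 1e-6)
  # ... and that slope exponentiates to the 2x2 odds ratio
  expect_equal(weight_to_odds_ratio(fit$coefficients[["a"]]),
               (0.6 / 0.4) / (0.1 / 0.9), tolerance = 1e-6)

  # one configuration per free parameter: exact closed form
  design <- rbind(c(0, 0, 0, 0), diag(4))
  set.seed(5)
  for (i in 1:5) {
    r <- round(runif(5, 0.05, 0.95) * 200) / 200  # realized cell rates
    fit_i <- fit_logistic(partial_training_set(design, r, 200))
    expect_equal(unname(fit_i$coefficients),
                 c(qlogis(r[1]), qlogis(r[2:5]) - qlogis(r[1])),
                 tolerance = 1e-6)
    expect_true(fit_i$converged)
  }
})

test_that("a cue-free reward rate of one half yields near-zero coefficients", {
  flat <- manual_training_set(rep(0.5, 16), 100)
  fit <- fit_logistic(flat)
  expect_true(all(abs(fit$coefficients) < 1e-8))
})

test_that("logistic fit flags degenerate and separated sets", {
  expect_error(fit_logistic(manual_training_set(rep(0, 16), 10)),
               "degenerate")
  sep <- partial_training_set(rbind(c(0, 0, 0, 0), c(1, 0, 0, 0)),
                              c(0, 1), 50)
  fit_sep <- suppressWarnings(fit_logistic(sep))
  expect_true(fit_sep$separation)
  expect_false(fit_sep$converged)
})

test_that("structure fit scores a perceptron against regression coefficients", {
  toy_rates <- expected_reward_probability(sim1_model(0.05))
  fit <- fit_logistic(manual_training_set(toy_rates, 100))
  co <- fit$coefficients
  p_same <- perceptron(co[c("a", "b", "x", "y")], bias = co[["intercept"]])
  expect_equal(structure_fit_r2(p_same, fit), 1)
  p_off <- perceptron(co[c("a", "b", "x", "y")] + 0.3,
                      bias = co[["intercept"]] + 0.3)
  expect_equal(structure_fit_r2(p_off, fit), 1)
})

test_that("odds-ratio transform inverts the log scale", {
  expect_equal(weight_to_odds_ratio(0), 1)
  expect_equal(weight_to_odds_ratio(log(4)), 4)
  w <- c(-2, -0.5, 0.1, 3)
  expect_equal(log(weight_to_odds_ratio(w)), w)
  expect_error(weight_to_odds_ratio(Inf))
})

test_that("conditional dependence is zero for exactly proportional tables", {
  # reward depends on A only: X and Y stay independent in both strata
  rates <- ifelse(cue_patterns()[, "a"] == 1, 0.5, 0.25)
  ts <- manual_training_set(rates, 100)
  dep <- conditional_dependence(ts)
  expect_equal(dep$chi2_rewarded, 0)
  expect_equal(dep$chi2_unrewarded, 0)
  expect_equal(dep$total, 0)
})

test_that("stratified chi-squares match the classical test statistic", {
  ts <- generate_training_set(sim2_model("and", 0.6), 100, seed = 14)
  dep <- conditional_dependence(ts)
  for (tv in 0:1) {
    sub <- ts$rows[ts$rows$target == tv, ]
    tab <- table(factor(sub$x, 0:1), factor(sub$y, 0:1))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    got <- if (tv == 1) dep$chi2_rewarded else dep$chi2_unrewarded
    expect_equal(got, unname(ref))
  }
  expect_equal(dep$total, dep$chi2_rewarded + dep$chi2_unrewarded)
})

test_that("dependence score ignores row order and A/B relabeling", {
  ts <- generate_training_set(sim2_model("xor", 0.6), 60, seed = 4)
  shuffled <- ts
  shuffled$rows <- ts$rows[withr::with_seed(1, sample(nrow(ts$rows))), ]
  expect_equal(conditional_dependence(shuffled)$total,
               conditional_dependence(ts)$total)
  swapped <- ts
  swapped$rows[, c("a", "b")] <- ts$rows[, c("b", "a")]
  expect_equal(conditional_dependence(swapped)$total,
               conditional_dependence(ts)$total)
})

test_that("zero-margin strata contribute zero by convention", {
  # rewards only ever occur when X is present: the rewarded stratum has a
  # zero column margin
  rates <- ifelse(cue_patterns()[, "x"] == 1, 0.5, 0)
  ts <- manual_training_set(rates, 20)
  dep <- conditional_dependence(ts)
  expect_equal(dep$chi2_rewarded, 0)
  all0 <- manual_training_set(rep(0, 16), 5)
  expect_equal(conditional_dependence(all0)$chi2_rewarded, 0)
})

test_that("dependence ordering across gate conditions matches expectation", {
  mean_dep <- function(kind, prob) {
    mean(sapply(1:5, function(s) {
      conditional_dependence(
        generate_training_set(sim2_model(kind, prob), 100,
                              seed = 1000 + s))$total
    }))
  }
  d <- c(and6 = mean_dep("and", 0.6), and1 = mean_dep("and", 0.1),
         xor6 = mean_dep("xor", 0.6), xor1 = mean_dep("xor", 0.1))
  expect_true(d[["xor6"]] > d[["and6"]])
  expect_true(d[["and6"]] > d[["xor1"]])
  expect_true(d[["xor1"]] > d[["and1"]])
})
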