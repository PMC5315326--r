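test_that("expected reward probability follows the addition rule", {
  m1 <- sim1_model()
  expect_equal(expected_reward_probability(m1, c(0, 0, 0, 0)), 0)
  # two independent sources: 0.2 + 0.4 - 0.2*0.4
  expect_equal(expected_reward_probability(m1, c(1, 1, 0, 0)), 0.52)
  expect_equal(expected_reward_probability(m1, c(0, 0, 1, 1)),
               1 - 0.4 * 0.2)
  expect_equal(expected_reward_probability(m1, c(1, 1, 1, 1)),
               1 - 0.8 * 0.6 * 0.4 * 0.2)

  and6 <- sim2_model("and", 0.6)
  expect_equal(expected_reward_probability(and6, c(0, 0, 1, 1)), 0.6)
  expect_equal(expected_reward_probability(and6, c(0, 0, 1, 0)), 0)
  expect_equal(expected_reward_probability(and6, c(1, 0, 1, 1)),
               1 - 0.8 * 0.4)

  xor6 <- sim2_model("xor", 0.6)
  expect_equal(expected_reward_probability(xor6, c(0, 0, 1, 0)), 0.6)
  expect_equal(expected_reward_probability(xor6, c(0, 0, 0, 1)), 0.6)
  expect_equal(expected_reward_probability(xor6, c(0, 0, 1, 1)), 0)

  base <- sim1_model(baseline_prob = 0.05)
  expect_equal(expected_reward_probability(base, c(0, 0, 0, 0)), 0.05)
  # baseline applies only to the all-absent pattern
  expect_equal(expected_reward_probability(base, c(1, 0, 0, 0)), 0.2)
})

test_that("complement-product form matches inclusion-exclusion expansion", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(3)
    m2 <- reward_model(c(a = p[1], b = p[2]))
    expect_equal(expected_reward_probability(m2, c(1, 1, 0, 0)),
                 p[1] + p[2] - p[1] * p[2])
    m3 <- reward_model(c(a = p[1], b = p[2], x = p[3]))
    expect_equal(expected_reward_probability(m3, c(1, 1, 1, 0)),
                 p[1] + p[2] + p[3] - p[1] * p[2] - p[1] * p[3] -
                   p[2] * p[3] + p[1] * p[2] * p[3])
  }
})

test_that("expected probability is monotone in each source probability", {
  set.seed(7)
  pats <- cue_patterns()
  for (i in 1:10) {
    p <- runif(2)
    g <- runif(1)
    eps <- runif(1, 0, 1 - max(p, g))
    lo <- reward_model(c(a = p[1], b = p[2]),
                       gate = list(kind = "xor", prob = g))
    hi_a <- reward_model(c(a = p[1] + eps, b = p[2]),
                         gate = list(kind = "xor", prob = g))
    hi_g <- reward_model(c(a = p[1], b = p[2]),
                         gate = list(kind = "xor", prob = g + eps))
    expect_true(all(expected_reward_probability(hi_a, pats) >=
                      expected_reward_probability(lo, pats)))
    expect_true(all(expected_reward_probability(hi_g, pats) >=
                      expected_reward_probability(lo, pats)))
  }
})

test_that("reward model rejects malformed inputs", {
  expect_error(reward_model(c(a = 1.3)), "probabilities")
  expect_error(reward_model(c(q = 0.5)), "named")
  expect_error(reward_model(c(x = 0.5),
                            gate = list(kind = "and", prob = 0.6)),
               "independent lottery")
  expect_error(reward_model(gate = list(kind = "nand", prob = 0.6)))
})

test_that("generation is reproducible and respects degenerate models", {
  m <- sim1_model()
  a <- generate_training_set(m, 50, seed = 123)
  b <- generate_training_set(m, 50, seed = 123)
  expect_identical(a$rows, b$rows)
  expect_false(identical(
    a$rows, generate_training_set(m, 50, seed = 124)$rows))

  zero <- reward_model(c(a = 0, b = 0, x = 0, y = 0))
  expect_true(all(generate_training_set(zero, 100, 1)$rows$target == 0L))

  det <- reward_model(gate = list(kind = "and", prob = 1))
  ts <- generate_training_set(det, 25, 1)
  expect_identical(ts$rows$target, as.integer(ts$rows$x & ts$rows$y))
})

test_that("observed rates fall in central 99% binomial intervals", {
  ts <- generate_training_set(sim1_model(), 100, seed = 2026)
  obs <- empirical_pattern_frequencies(ts)
  expected <- expected_reward_probability(sim1_model())
  lo <- qbinom(0.005, 100, expected) / 100
  hi <- qbinom(0.995, 100, expected) / 100
  expect_true(all(obs >= lo & obs <= hi))
})

test_that("generator is calibrated: mean rates converge to expectation", {
  m <- sim2_model("xor", 0.6)
  expected <- expected_reward_probability(m)
  rates <- sapply(1:30, function(s) {
    empirical_pattern_frequencies(generate_training_set(m, 50, seed = s))
  })
  mean_rates <- rowMeans(rates)
  # SE of a mean of 30 sets of 50 trials is at most 0.5/sqrt(1500) ~ 0.013
  expect_true(all(abs(mean_rates - expected) < 5 * 0.013))
})

test_that("validation passes exact sets and flags corrupted ones", {
  single <- reward_model(c(a = 0.5))  # every expected rate is 0 or 0.5
  exact <- manual_training_set(
    expected_reward_probability(single), 100, model = single)
  rep_exact <- validate_training_set(exact)
  expect_true(all(rep_exact$chi2 == 0))
  expect_true(all(rep_exact$pass))

  # force every A-only trial to be rewarded: chi2 = 80^2/20 + 80^2/80 = 400
  bad <- generate_training_set(sim1_model(), 100, seed = 5)
  sel <- bad$rows$a == 1 & bad$rows$b == 0 & bad$rows$x == 0 &
    bad$rows$y == 0
  bad$rows$target[sel] <- 1L
  rep_bad <- validate_training_set(bad, alpha = 0.05)
  i <- which(rep_bad$pattern == "R|A~B~X~Y")
  expect_equal(rep_bad$chi2[i], 400)
  expect_false(rep_bad$pass[i])

  # a freshly drawn set typically passes everywhere
  expect_true(all(validate_training_set(
    generate_training_set(sim1_model(), 100, seed = 42))$pass))
})

test_that("zero-probability configurations pass only when degenerate", {
  m <- sim2_model("and", 0.6)  # most configurations have probability 0
  ts <- generate_training_set(m, 100, seed = 9)
  rep0 <- validate_training_set(ts)
  zero_rows <- rep0$expected_rate == 0
  expect_true(any(zero_rows))
  expect_true(all(rep0$pass[zero_rows] == (rep0$observed_rate[zero_rows] == 0)))

  ts$rows$target[which(ts$rows$a == 0 & ts$rows$b == 0 & ts$rows$x == 0 &
                         ts$rows$y == 0)[1]] <- 1L
  expect_false(validate_training_set(ts)$pass[1])
})

test_that("regeneration loop returns a validated set", {
  ts <- generate_valid_training_set(sim1_model(), 100, seed = 77)
  expect_true(all(validate_training_set(ts)$pass))
  expect_error(
    generate_valid_training_set(sim1_model(), 2, seed = 1, alpha = 0.9999,
                                max_attempts = 2),
    "attempts")
})
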