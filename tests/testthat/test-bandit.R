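test_that("softmax is uniform at zero gain, translation-invariant, overflow-safe", {
  expect_equal(softmax_probabilities(c(2, 2, 2), 5), rep(1 / 3, 3))
  expect_equal(softmax_probabilities(c(1, 4, 9), 0), rep(1 / 3, 3))
  p <- softmax_probabilities(c(1, 2, 3), 1.3)
  expect_equal(sum(p), 1)
  expect_equal(softmax_probabilities(c(1, 2, 3) + 57, 1.3), p)
  expect_equal(softmax_probabilities(c(1e4, 1e4 + 1), 1),
               c(1 / (1 + exp(1)), 1 / (1 + exp(-1))))
  # two-value reduction to the logistic of the scaled difference
  d <- 0.7; beta <- 4
  expect_equal(softmax_probabilities(c(0, d), beta)[2],
               1 / (1 + exp(-beta * d)))
  expect_error(softmax_probabilities(numeric(0), 1), "non-empty")
})

test_that("win-shift falls with dopamine and rises with risk", {
  # below the attention threshold all posterior means collapse to the prior
  flat <- winshift_sim(0.5, "low")
  expect_equal(flat$winshift, 2 / 3)
  expect_equal(winshift_sim(0.5, "high")$winshift, 2 / 3)

  for (risk in c("low", "high")) {
    ws <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9),
                 function(da) winshift_sim(da, risk)$winshift, numeric(1))
    expect_true(all(diff(ws) < 0))
  }
  for (da in c(0.6, 0.75, 0.9)) {
    expect_gt(winshift_sim(da, "high")$winshift,
              winshift_sim(da, "low")$winshift)
  }
  # exploitation monotonicity: p(best) = 1 - winshift non-decreasing in DA
  da_grid <- seq(0.3, 1.2, by = 0.05)
  p_best <- 1 - vapply(da_grid, function(da) winshift_sim(da, "low")$winshift,
                       numeric(1))
  expect_true(all(diff(p_best) >= 0))
})

test_that("feedback accuracy is a posterior tail mass with the expected asymmetry", {
  # prior mean at 0.5 makes the construction symmetric: zero relative accuracy
  expect_equal(relative_accuracy(0.5), 0, tolerance = 1e-12)
  expect_gt(relative_accuracy(0.9), 0)
  expect_lt(relative_accuracy(0.1), 0)
  # strictly increasing up to the baseline DA of 0.9; in the infinite-
  # precision limit both accuracies approach 1, so the difference flattens
  ra <- vapply(seq(0.1, 0.9, by = 0.1), relative_accuracy, numeric(1))
  expect_true(all(diff(ra) > 0))

  # quadrature oracle: integrate the posterior density directly
  da <- 0.9; kappa <- 0.1; lam0 <- 5
  lam <- max(0, 2 * da / kappa - lam0)
  w <- lam / (lam + lam0)
  post_mean <- w * 1 + (1 - w) * da
  post_sd <- 1 / sqrt(lam + lam0)
  quad <- integrate(function(x) dnorm(x, post_mean, post_sd), 0.5, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(feedback_accuracy(0.9, 1), quad, tolerance = 1e-6)
  expect_error(feedback_accuracy(0.9, 0.5), "outcome")
})

test_that("precision modulation is behaviorally identical to softmax gain control", {
  prior <- gaussian_belief(0.5, 1)
  # w = 1 limit: posterior difference equals the raw difference
  res <- gain_equivalence_check(1e12, 4, prior = prior)
  expect_equal(res$p_precision_route,
               1 / (1 + exp(-4 * 1)), tolerance = 1e-9)
  # w = 0.5 at beta 4 matches full precision at beta 2
  lam_half <- 1 # lambda = lambda0 gives w = 0.5
  res <- gain_equivalence_check(lam_half, 4, prior = prior)
  expect_equal(res$p_precision_route, 1 / (1 + exp(-2 * 1)))

  set.seed(8)
  res <- gain_equivalence_check(runif(10, 0.1, 20), runif(10, 0.5, 8),
                                prior = prior)
  expect_lt(max(res$discrepancy), 1e-12)
  expect_true(all(res$equivalent))
})

test_that("risk conditions carry the documented arm structure", {
  low <- bandit_arms("low")
  high <- bandit_arms("high")
  expect_equal(low$reward_probability, c(7 / 8, 1 / 16, 1 / 16))
  expect_equal(high$reward_probability, c(5 / 8, 3 / 16, 3 / 16))
  expect_equal(low$expected_value, low$reward_probability)
  # both conditions share the same mean value but high risk a smaller spread
  expect_equal(mean(low$expected_value), mean(high$expected_value))
  expect_lt(diff(range(high$expected_value)), diff(range(low$expected_value)))
})
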