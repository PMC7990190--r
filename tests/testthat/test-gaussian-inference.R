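test_that("likelihood weight matches the precision-ratio form and its bounds", {
  expect_equal(likelihood_weight(1, 1), 0.5)
  expect_equal(likelihood_weight(0, 5), 0)
  expect_equal(likelihood_weight(1, 1, c = 2), 2 / 3)

  lam <- seq(0, 50, by = 0.5)
  w <- likelihood_weight(lam, 2)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) > 0))          # monotone in lambda
  expect_true(all(likelihood_weight(3, 2, c = c(0.5, 1, 2, 4)) ==
                    cummax(likelihood_weight(3, 2, c = c(0.5, 1, 2, 4)))))
  expect_error(likelihood_weight(1, 0), "lambda_prior")
})

test_that("posterior update is conjugate: weighted mean, additive precision", {
  prior <- gaussian_belief(0, 1)
  expect_equal(posterior(prior, 2, 1)$mean, 1)
  expect_equal(posterior(prior, 123, 0)$mean, 0)      # no signal -> prior
  expect_equal(posterior(prior, 2, 1e12)$mean, 2, tolerance = 1e-9)
  expect_error(posterior(prior, 2, -1), "lambda_est")

  set.seed(42)
  for (i in 1:20) {
    mu0 <- rnorm(1); lam0 <- runif(1, 0.1, 5)
    m <- rnorm(1, mu0, 2); lam <- runif(1, 0, 5)
    post <- posterior(gaussian_belief(mu0, lam0), m, lam)
    expect_equal(post$precision, lam0 + lam)
    expect_true(post$mean >= min(mu0, m) - 1e-12 &&
                  post$mean <= max(mu0, m) + 1e-12)
  }
})

test_that("conditional error has the variance-plus-shrinkage-bias form", {
  prior <- gaussian_belief(0, 1)
  ch <- miscalibrated_channel(1, 1)
  expect_equal(conditional_error(0, prior, ch), 0.25)
  expect_equal(conditional_error(2, prior, ch), 1.25)
  big <- miscalibrated_channel(1e12, 1e12)
  expect_lt(conditional_error(2, prior, big), 1e-6)
  expect_error(conditional_error(0, prior, miscalibrated_channel(0, 0)),
               "lambda_true")
})

test_that("closed-form errors agree with Monte-Carlo encode-decode oracles", {
  oracle <- mc_conditional_error(source = 2, prior_mean = 0, lambda_prior = 1,
                                 lambda_true = 1, lambda_est = 1, seed = 11)
  expect_lt(abs(oracle$mean - 1.25), 3 * oracle$se)

  oracle <- mc_marginal_error(prior_mean = 0, lambda_prior = 1,
                              lambda_true = 1, lambda_est = 2, seed = 12)
  expect_equal(marginal_error(miscalibrated_channel(1, 2), 1), 5 / 9)
  expect_lt(abs(oracle$mean - 5 / 9), 3 * oracle$se)

  set.seed(7)
  for (i in 1:20) {
    lam0 <- runif(1, 0.2, 4); lam <- runif(1, 0.2, 4)
    cc <- runif(1, 0.3, 3); mu0 <- rnorm(1)
    closed <- marginal_error(miscalibrated_channel(lam, cc * lam), lam0)
    mc <- mc_marginal_error(mu0, lam0, lam, cc * lam, seed = 100 + i)
    expect_lt(abs(mc$mean - closed), 3 * mc$se)
  }
})

test_that("calibrated marginal error collapses to the posterior variance", {
  set.seed(3)
  for (i in 1:25) {
    lam <- runif(1, 0, 10); lam0 <- runif(1, 0.05, 10)
    err <- marginal_error(miscalibrated_channel(lam, lam), lam0)
    expect_lt(abs(err - 1 / (lam + lam0)), 1e-12)
  }
})

test_that("any miscalibration strictly worsens the marginal error", {
  set.seed(4)
  for (i in 1:15) {
    lam <- runif(1, 0.1, 8); lam0 <- runif(1, 0.1, 8)
    base <- marginal_error(miscalibrated_channel(lam, lam), lam0)
    for (cc in c(0.2, 0.5, 2, 5)) {
      expect_gt(marginal_error(miscalibrated_channel(lam, cc * lam), lam0),
                base)
    }
  }
})

test_that("grid search finds the calibrated channel as the error minimum", {
  expect_equal(optimal_miscalibration(1, 1), 1)
  expect_equal(optimal_miscalibration(10, 0.5), 1)
  err_at <- function(cc) marginal_error(miscalibrated_channel(1, cc), 1)
  expect_lt(err_at(1), err_at(0.5))
  expect_lt(err_at(1), err_at(2))
  expect_error(optimal_miscalibration(1, 1, numeric(0)), "non-empty")
})

test_that("belief constructors validate and derive entropy consistently", {
  expect_error(gaussian_belief(0, -1), "precision")
  expect_error(miscalibrated_channel(-1, 1), "lambda_true")
  expect_equal(belief_entropy(gaussian_belief(0, 1)),
               0.5 * log(2 * pi * exp(1)))
  expect_equal(miscalibration_factor(miscalibrated_channel(2, 1)), 0.5)
  expect_error(miscalibration_factor(miscalibrated_channel(0, 1)), "undefined")
  set.seed(5)
  draws <- encode_signal(2e4, 3, miscalibrated_channel(4, 4))
  expect_equal(mean(draws), 3, tolerance = 0.02)
  expect_equal(var(draws), 0.25, tolerance = 0.05)
})
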