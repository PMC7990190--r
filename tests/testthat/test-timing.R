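test_that("objective and subjective time are exact inverses", {
  tm <- time_mapping(2.5)
  expect_equal(to_subjective(0, tm), 0)
  expect_equal(to_subjective(exp(1) - 1, time_mapping(1)), 1)
  for (mu in c(1, 7, 17)) {
    expect_equal(from_subjective(to_subjective(mu, tm), tm), mu,
                 tolerance = 1e-9)
  }
  expect_error(to_subjective(-1, tm), "duration")
})

test_that("clock gain realizes the prescribed objective-time precision", {
  expect_equal(clock_gain_from_precision(1, 0, l = 1), 1)
  expect_equal(clock_gain_from_precision(2, 5) / clock_gain_from_precision(1, 5),
               sqrt(2))
  # root-finding oracle: eta whose delta-method precision at the reference
  # equals lambda*
  lam0 <- 1 / ((21 - 8) / 2.5)^2
  lam_star <- optimal_precision(attention_problem(1, 0.05, lam0))
  ref <- 14.5
  eta_oracle <- uniroot(function(eta) eta^2 / (ref + 1)^2 - lam_star,
                        c(1e-3, 1e4), tol = 1e-12)$root
  expect_equal(clock_gain_from_precision(lam_star, ref, l = 1), eta_oracle,
               tolerance = 1e-6)
  # floor keeps the clock running at zero prescribed precision
  expect_gt(clock_gain_from_precision(0, 10), 0)
})

test_that("reproduction reflects the encode/decode gain ratio", {
  flat <- gaussian_belief(0, 0)
  expect_equal(reproduce_interval(7, 2, 2, flat), 7, tolerance = 1e-12)
  # fast decoding clock underproduces; closed form vs stepwise pipeline
  expect_equal(reproduce_interval(7, 1, 1.2, flat), 8^(1 / 1.2) - 1,
               tolerance = 1e-12)
  expect_lt(reproduce_interval(7, 1, 1.2, flat), 7)
  # slow decoding clock overproduces
  expect_gt(reproduce_interval(7, 1, 0.8, flat), 7)
})

test_that("an informative prior pulls reproductions toward its mean", {
  eta <- 10
  tm <- time_mapping(eta)
  prior_obj <- gaussian_belief(14.5, 1 / 5.2^2)
  sp <- subjective_prior(prior_obj, tm)
  for (mu in c(8, 21)) {
    t_hat <- reproduce_interval(mu, eta, eta, sp)
    lo <- min(mu, prior_obj$mean); hi <- max(mu, prior_obj$mean)
    expect_gte(t_hat, lo - 1e-9)
    expect_lte(t_hat, hi + 1e-9)
  }
})

test_that("central tendency: low DA compresses toward the prior, high DA is near-veridical", {
  res <- central_tendency_sim(c(8, 21), c(0.2, 1))
  lo <- res[res$da == 0.2, ]
  hi <- res[res$da == 1, ]
  # low DA: short overproduced, long underproduced
  expect_gt(lo$reproduction_s[lo$duration_s == 8], 8)
  expect_lt(lo$reproduction_s[lo$duration_s == 21], 21)
  # high DA closer to veridical than low DA for both durations
  expect_true(all(abs(hi$reproduction_s - hi$duration_s) <
                    abs(lo$reproduction_s - lo$duration_s)))

  # shrinkage monotonicity: compression factor rises with DA
  levels <- c(0.2, 0.5, 1)
  res3 <- central_tendency_sim(c(8, 21), levels)
  prior_mean <- 14.5
  fac <- vapply(levels, function(da) {
    r <- res3[res3$da == da & res3$duration_s == 21, ]
    (r$reproduction_s - prior_mean) / (21 - prior_mean)
  }, numeric(1))
  expect_true(all(diff(fac) > 0))
})

test_that("acute decoding DA orders blocked reproductions as clock-speed shifts", {
  res <- clock_speed_sim(c(7, 17), c(0.8, 1, 1.2))
  for (mu in c(7, 17)) {
    r <- res[res$duration_s == mu, ]
    expect_equal(r$reproduction_s[r$da == 1], mu, tolerance = 1e-6)
    expect_lt(r$reproduction_s[r$da == 1.2], mu)
    expect_gt(r$reproduction_s[r$da == 0.8], mu)
    expect_true(all(diff(r$reproduction_s[order(r$da)]) < 0))
  }
})

test_that("sampled reproductions show Weber-like linear SD growth and no mean bias", {
  set.seed(99)
  tm <- time_mapping(40)
  durations <- seq(2, 40, by = 2)
  draws <- sample_reproductions(2000, durations, tm)
  stats <- aggregate(reproduction_s ~ duration_s, draws,
                     function(x) c(sd = sd(x), mean = mean(x)))
  sds <- stats$reproduction_s[, "sd"]
  fit <- lm(sds ~ stats$duration_s)
  expect_gt(summary(fit)$r.squared, 0.95)
  # encode/decode symmetry: mean reproduction unbiased within MC error
  m7 <- draws$reproduction_s[draws$duration_s == 10]
  expect_lt(abs(mean(m7) - 10), 3 * sd(m7) / sqrt(length(m7)) + 10 / (2 * 40^2))
})
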