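test_that("mutual information equals the prior-posterior entropy drop", {
  expect_equal(mutual_information(0, 2), 0)
  expect_equal(mutual_information(3, 3), 0.5 * log(2))
  # entropy-difference oracle, exact
  lam <- 3; lam0 <- 1
  drop <- belief_entropy(gaussian_belief(0, lam0)) -
    belief_entropy(gaussian_belief(0, lam0 + lam))
  expect_equal(mutual_information(lam, lam0), drop)
  expect_equal(mutual_information(lam, lam0), log(2))
  expect_true(all(diff(mutual_information(seq(0, 10, 0.1), 1)) > 0))
  expect_error(mutual_information(-1, 1), "lambda_like")
})

test_that("the attentional objective combines weighted error and info cost", {
  pr <- attention_problem(1, 0.5, 0.5)
  expect_equal(attentional_objective(0, pr), 1 / 0.5)
  # no incentive: cost only, minimized at zero precision
  pr0 <- attention_problem(0, 0.5, 0.5)
  lam_grid <- seq(0, 20, by = 0.01)
  vals <- attentional_objective(lam_grid, pr0)
  expect_equal(lam_grid[which.min(vals)], 0)
  # dense-grid oracle for one interior evaluation
  expect_equal(attentional_objective(3.5, pr),
               1 / (3.5 + 0.5) + 0.5 * 0.5 * log(1 + 3.5 / 0.5))
})

test_that("closed-form optimal precision matches numerical minimization", {
  expect_equal(optimal_precision(attention_problem(0.1, 0.5, 0.5)), 0)
  expect_equal(optimal_precision(attention_problem(0.9, 0.1, 10)), 8)
  expect_equal(optimal_precision(attention_problem(1, 0.5, 0.5)), 3.5)
  expect_equal(numeric_lambda_star(0.9, 0.1, 10), 8, tolerance = 1e-6)
  expect_equal(numeric_lambda_star(1, 0.5, 0.5), 3.5, tolerance = 1e-6)

  set.seed(21)
  for (i in 1:50) {
    R <- runif(1, 0, 3); kappa <- runif(1, 0.05, 1); lam0 <- runif(1, 0.1, 12)
    closed <- optimal_precision(attention_problem(R, kappa, lam0))
    expect_lt(abs(closed - numeric_lambda_star(R, kappa, lam0)), 1e-5)
  }
})

test_that("precision-incentive curve is piecewise linear with slope 2/kappa", {
  kappa <- 0.5; lam0 <- 0.5
  curve <- precision_incentive_curve(seq(0, 2, by = 0.01), kappa, lam0)
  kink <- kappa * lam0 / 2
  expect_true(all(curve$lambda_star[curve$R <= kink] == 0))
  above <- curve[curve$R > kink + 0.05, ]
  slopes <- diff(above$lambda_star) / diff(above$R)
  expect_equal(slopes, rep(2 / kappa, length(slopes)), tolerance = 1e-9)
  # threshold property: lambda* = 0 iff 2R/kappa <= lambda0
  expect_true(all((curve$lambda_star == 0) == (2 * curve$R / kappa <= lam0)))
  # posterior-precision matching above threshold
  pos <- curve[curve$lambda_star > 0, ]
  expect_equal(pos$lambda_star + lam0, 2 * pos$R / kappa, tolerance = 1e-12)
})

test_that("context maps to incentive via dopamine or the contingency ratio", {
  expect_equal(incentive_from_context(dopamine_level = 0.9), 0.9)
  base <- incentive_from_context(free_reward_rate = 0.01,
                                 contingent_reward_rate = 0.01)
  expect_equal(incentive_from_context(free_reward_rate = 0.02,
                                      contingent_reward_rate = 0.01),
               base / 2)
  expect_equal(incentive_from_context(free_reward_rate = 0.01,
                                      contingent_reward_rate = 0.02),
               base * 2)
  expect_error(incentive_from_context(free_reward_rate = 0,
                                      contingent_reward_rate = 0.01),
               "free_reward_rate")
})

test_that("bounded true precision turns monotone improvement into an inverted U", {
  R_grid <- seq(0, 5, by = 0.05)
  free <- bounded_performance_curve(R_grid, 0.5, 0.5, lambda_max = Inf)
  expect_true(all(diff(free$error) <= 1e-12))

  capped <- bounded_performance_curve(R_grid, 0.5, 0.5, lambda_max = 4)
  i_min <- which.min(capped$error)
  expect_gt(i_min, 1)
  expect_lt(i_min, nrow(capped))
  # at the R where lambda_est hits the cap exactly the channel is calibrated
  R_sat <- (4 + 0.5) * 0.5 / 2
  row <- bounded_performance_curve(R_sat, 0.5, 0.5, lambda_max = 4)
  expect_equal(row$error, 1 / (4 + 0.5))
  expect_error(bounded_performance_curve(R_grid, 0.5, 0.5, lambda_max = 0),
               "lambda_max")
})

test_that("attention problem tidiers expose terms and the optimum", {
  pr <- attention_problem(1, 0.5, 0.5)
  td <- tidy(pr)
  expect_equal(td$value[td$term == "lambda_star"], 3.5)
  gl <- glance(pr)
  expect_equal(gl$posterior_precision, 4)
  expect_true(gl$attending)
})
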