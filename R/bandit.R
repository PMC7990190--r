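#' Softmax choice probabilities
#'
#' Standard softmax action selection over estimated values with inverse
#' temperature beta, evaluated with max-subtraction so large values cannot
#' overflow. beta = 0 gives the uniform policy; adding a constant to every
#' value leaves the probabilities unchanged.
#'
#' @param values Numeric vector of (posterior) action values.
#' @param beta Non-negative inverse temperature.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_probabilities(c(1, 2, 3), beta = 1)
#' @export
softmax_probabilities <- function(values, beta) {
  if (length(values) == 0) stop("`values` must be non-empty.", call. = FALSE)
  check_nonneg(beta, "beta")
  z <- beta * (values - max(values))
  e <- exp(z)
  e / sum(e)
}

#' Three-armed bandit risk condition
#'
#' Arm descriptions for the win-shift experiment: one good lever and two poor
#' levers, all paying `magnitude` with the given probabilities. `"low"` risk
#' is (7/8, 1/16, 1/16); `"high"` risk is (5/8, 3/16, 3/16). Arm values are
#' the expected rewards (probability times magnitude).
#'
#' @param risk `"low"` or `"high"`.
#' @param magnitude Reward magnitude per success.
#' @return A tibble with columns `arm`, `reward_probability`,
#'   `reward_magnitude`, `expected_value`.
#' @export
bandit_arms <- function(risk = c("low", "high"), magnitude = 1) {
  risk <- match.arg(risk)
  probs <- switch(risk,
                  low = c(7 / 8, 1 / 16, 1 / 16),
                  high = c(5 / 8, 3 / 16, 3 / 16))
  tibble::tibble(
    arm = paste0("arm", seq_along(probs)),
    reward_probability = probs,
    reward_magnitude = magnitude,
    expected_value = probs * magnitude
  )
}

#' Win-shift probability under rational inattention
#'
#' Static decoding account of exploration: the agent holds a shared Gaussian
#' prior over arm values (mean = the across-arm mean expected value unless
#' given), buys likelihood precision lambda* = max(0, 2 DA / kappa - lambda0),
#' and forms a posterior mean per arm by shrinking its expected value toward
#' the prior. Choice follows a softmax over the posterior means; the win-shift
#' probability is the chance of *not* re-selecting the just-rewarded best
#' arm, i.e. 1 - p(best arm). Low DA buys little precision, posterior means
#' collapse toward the prior, and the agent explores; riskier conditions
#' (smaller spread in expected value) raise win-shift at every DA.
#'
#' @param dopamine_level Strictly positive tonic DA; the incentive R.
#' @param risk `"low"` or `"high"` risk condition (see [bandit_arms()]).
#' @param info_cost kappa.
#' @param prior_precision lambda0 of the shared prior over arm values.
#' @param beta Softmax inverse temperature.
#' @param magnitude Reward magnitude.
#' @param prior_mean Optional prior mean; defaults to the mean expected value.
#' @return A one-row tibble with columns `da`, `risk`, `winshift`.
#' @examples
#' winshift_sim(0.9, "low")
#' @export
winshift_sim <- function(dopamine_level, risk = c("low", "high"),
                         info_cost = 0.1, prior_precision = 10, beta = 4,
                         magnitude = 1, prior_mean = NULL) {
  risk <- match.arg(risk)
  check_pos(dopamine_level, "dopamine_level")
  arms <- bandit_arms(risk, magnitude)
  if (is.null(prior_mean)) prior_mean <- mean(arms$expected_value)
  R <- incentive_from_context(dopamine_level = dopamine_level)
  lam_star <- optimal_precision(attention_problem(R, info_cost, prior_precision))
  prior <- gaussian_belief(prior_mean, prior_precision)
  post_means <- vapply(arms$expected_value,
                       function(v) posterior(prior, v, lam_star)$mean,
                       numeric(1))
  p <- softmax_probabilities(post_means, beta)
  best <- which.max(arms$expected_value)
  tibble::tibble(da = dopamine_level, risk = risk, winshift = 1 - p[best])
}

#' Accuracy after positive or negative feedback
#'
#' Learning-asymmetry construction: the outcome of a trial is 1 (reward) or 0
#' (punishment). The agent's prior over the outcome value is centred on the
#' tonic DA level (high DA means high expected reward in the context) with
#' precision lambda0; the encoded outcome has likelihood precision lambda* =
#' max(0, 2 DA / kappa - lambda0). Accuracy is the posterior probability mass
#' on the correct side of 0.5 — right of 0.5 for a reward, left for a
#' punishment — computed with the Gaussian CDF.
#'
#' @param dopamine_level Strictly positive DA; prior mean and incentive both.
#' @param outcome 0 (punishment) or 1 (reward).
#' @param info_cost kappa.
#' @param prior_precision lambda0.
#' @return Accuracy in `[0, 1]`.
#' @export
feedback_accuracy <- function(dopamine_level, outcome, info_cost = 0.1,
                              prior_precision = 5) {
  check_pos(dopamine_level, "dopamine_level")
  if (!(is.numeric(outcome) && length(outcome) == 1L && outcome %in% c(0, 1))) {
    stop("`outcome` must be 0 or 1.", call. = FALSE)
  }
  R <- incentive_from_context(dopamine_level = dopamine_level)
  lam_star <- optimal_precision(attention_problem(R, info_cost, prior_precision))
  prior <- gaussian_belief(dopamine_level, prior_precision)
  post <- posterior(prior, outcome, lam_star)
  sd_post <- 1 / sqrt(post$precision)
  if (outcome == 1) {
    stats::pnorm(0.5, mean = post$mean, sd = sd_post, lower.tail = FALSE)
  } else {
    stats::pnorm(0.5, mean = post$mean, sd = sd_post, lower.tail = TRUE)
  }
}

#' Relative accuracy: positive minus negative feedback
#'
#' `accuracy(outcome = 1) - accuracy(outcome = 0)` at a given DA level.
#' Increases with DA and changes sign where the prior mean crosses 0.5: high
#' DA shifts beliefs toward expecting reward, so unexpected rewards are
#' learned better than omissions, and conversely under low DA.
#'
#' @inheritParams feedback_accuracy
#' @return Signed relative accuracy in `[-1, 1]`.
#' @examples
#' relative_accuracy(0.9) # > 0
#' relative_accuracy(0.1) # < 0
#' @export
relative_accuracy <- function(dopamine_level, info_cost = 0.1,
                              prior_precision = 5) {
  feedback_accuracy(dopamine_level, 1, info_cost, prior_precision) -
    feedback_accuracy(dopamine_level, 0, info_cost, prior_precision)
}

#' Equivalence of precision modulation and softmax gain control
#'
#' In the two-arm case the posterior-mean difference is w times the
#' likelihood-mean difference, so choice probabilities under weight w and
#' inverse temperature beta equal those under weight w' and temperature
#' beta * w / w' exactly: scaling decoding precision is behaviorally
#' indistinguishable from scaling the softmax gain. This function verifies
#' the identity over supplied (lambda, beta) pairs against the fully precise
#' channel (w = 1) with rescaled temperature.
#'
#' @param lambda_pairs Numeric vector of likelihood precisions to test.
#' @param beta_pairs Numeric vector (same length) of inverse temperatures.
#' @param mu_large,mu_small Likelihood means of the two arms.
#' @param prior A shared [gaussian_belief()].
#' @return A tibble with columns `lambda`, `beta`, `p_precision_route`,
#'   `p_gain_route`, `discrepancy`, plus the attribute check `all_equal`
#'   reported as column `equivalent` (discrepancy below 1e-12).
#' @export
gain_equivalence_check <- function(lambda_pairs, beta_pairs,
                                   mu_large = 1, mu_small = 0,
                                   prior = gaussian_belief(0.5, 1)) {
  stopifnot(length(lambda_pairs) == length(beta_pairs),
            inherits(prior, "gaussian_belief"))
  purrr::map2_dfr(lambda_pairs, beta_pairs, function(lam, beta) {
    w <- likelihood_weight(lam, prior$precision)
    d_post <- posterior(prior, mu_large, lam)$mean -
      posterior(prior, mu_small, lam)$mean
    p_precision <- 1 / (1 + exp(-beta * d_post))
    # gain route: undiluted difference, temperature rescaled by w
    p_gain <- 1 / (1 + exp(-(beta * w) * (mu_large - mu_small)))
    tibble::tibble(lambda = lam, beta = beta,
                   p_precision_route = p_precision,
                   p_gain_route = p_gain,
                   discrepancy = abs(p_precision - p_gain),
                   equivalent = abs(p_precision - p_gain) < 1e-12)
  })
}
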