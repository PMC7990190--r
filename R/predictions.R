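#' Training context for the transfer predictions
#'
#' Arms learned under a given controllability level: each arm's reward
#' magnitude is encoded with likelihood precision `encoding_precision` (1 for
#' high controllability, 0.1 for low) and shrunk toward the context's prior
#' mean (by default the mean of the experienced rewards).
#'
#' @param arm_rewards Reward magnitudes experienced in the context.
#' @param encoding_precision Likelihood precision lambda during training.
#' @param prior_precision lambda0 of the context prior.
#' @param prior_mean Prior mean; defaults to `mean(arm_rewards)`.
#' @return An object of class `training_context` with a `$estimates` tibble.
#' @examples
#' training_context(c(5, 10), encoding_precision = 1)$estimates
#' @export
training_context <- function(arm_rewards, encoding_precision,
                             prior_precision = 1,
                             prior_mean = mean(arm_rewards)) {
  stopifnot(is.numeric(arm_rewards), length(arm_rewards) >= 1)
  check_pos(encoding_precision, "encoding_precision")
  check_pos(prior_precision, "prior_precision")
  prior <- gaussian_belief(prior_mean, prior_precision)
  estimates <- tibble::tibble(
    reward = arm_rewards,
    estimate = vapply(arm_rewards,
                      function(r) posterior(prior, r, encoding_precision)$mean,
                      numeric(1))
  )
  structure(list(prior = prior, encoding_precision = encoding_precision,
                 estimates = estimates),
            class = "training_context")
}

#' Transfer choices between contexts of different controllability
#'
#' Arms yielding identical rewards are trained under high controllability
#' (precision 1; arms A1, B1) or low controllability (precision 0.1; arms A2,
#' B2), then paired across contexts at test. Central tendency compresses the
#' low-controllability estimates toward the prior mean more strongly, so for
#' the small-reward pair the low-controllability arm A2 looks *better* than
#' A1 (its estimate was pulled up), while for the large-reward pair the
#' high-controllability arm B1 looks better than B2. The direction flips
#' between pairs, so no uniform preference for a controllability level can
#' produce the pattern.
#'
#' @param high_ctx,low_ctx [training_context()] objects over the same arm
#'   rewards (ascending; first = small, last = large).
#' @param beta Softmax inverse temperature at test.
#' @return A tibble with one row per transfer pair: columns `pair`,
#'   `reward`, `estimate_high`, `estimate_low`, `p_high`, `p_low`.
#' @examples
#' hi <- training_context(c(5, 10), 1)
#' lo <- training_context(c(5, 10), 0.1)
#' train_and_transfer(hi, lo)
#' @export
train_and_transfer <- function(high_ctx, low_ctx, beta = 1) {
  stopifnot(inherits(high_ctx, "training_context"),
            inherits(low_ctx, "training_context"))
  if (!isTRUE(all.equal(high_ctx$estimates$reward, low_ctx$estimates$reward))) {
    stop("Contexts must be trained on matching arm magnitudes.", call. = FALSE)
  }
  purrr::map2_dfr(
    seq_len(nrow(high_ctx$estimates)), high_ctx$estimates$reward,
    function(i, r) {
      est_h <- high_ctx$estimates$estimate[i]
      est_l <- low_ctx$estimates$estimate[i]
      p <- softmax_probabilities(c(est_h, est_l), beta)
      tibble::tibble(pair = paste0("reward_", r), reward = r,
                     estimate_high = est_h, estimate_low = est_l,
                     p_high = p[1], p_low = p[2])
    }
  )
}

#' Estimated reward prediction error after a stochastic outcome
#'
#' A single arm pays a small or large reward (5 or 10) with equal
#' probability; the expected arm value is the prior mean (7.5). The received
#' outcome is estimated by shrinking it toward the prior with weight
#' w(lambda, lambda0), and the phasic prediction error is the estimated
#' outcome minus the expectation: RPE = w * (outcome - prior mean). Higher
#' encoding precision (high controllability) preserves more of the deviation,
#' so bursts are larger and dips deeper than under low controllability; the
#' sign is always that of the raw deviation.
#'
#' @param outcome Received reward magnitude.
#' @param encoding_precision lambda during learning.
#' @param prior A [gaussian_belief()] over the arm value.
#' @return Signed prediction error.
#' @examples
#' rpe_magnitude(10, 1)   #  1.25
#' rpe_magnitude(10, 0.1) #  about 0.23
#' @export
rpe_magnitude <- function(outcome, encoding_precision,
                          prior = gaussian_belief(7.5, 1)) {
  stopifnot(inherits(prior, "gaussian_belief"))
  check_pos(encoding_precision, "encoding_precision")
  posterior(prior, outcome, encoding_precision)$mean - prior$mean
}

#' Discriminating test: gain control vs rational-inattention decoding
#'
#' Two identical medium-reward arms are trained in different company: C1
#' beside a smaller reward (its context prior pulls its estimate down), C2
#' beside a larger one (estimate pulled up). At test the pair is presented
#' under low or high dopamine, and the two hypotheses disagree:
#'
#' * **Gain control** — the trained estimates are fixed and DA scales the
#'   softmax inverse temperature (beta 1 -> 10), amplifying the estimate gap:
#'   p(C2) *rises* with DA.
#' * **Rational inattention** — DA raises decoding precision (the estimated
#'   precision is multiplied by `decode_boost`), weakening the central
#'   tendency so both estimates migrate toward the true value and each other:
#'   p(C2) *falls* with DA.
#'
#' @param true_reward Common true magnitude of C1 and C2.
#' @param prior_mean_c1,prior_mean_c2 Context prior means.
#' @param encoding_precision lambda during training (both contexts).
#' @param prior_precision lambda0 of the context priors.
#' @param beta_low,beta_high Inverse temperatures for low/high DA under gain
#'   control (`beta_low` is also used under rational inattention).
#' @param decode_boost Multiplier on decoding precision under high DA for the
#'   rational-inattention hypothesis.
#' @return A tibble with columns `hypothesis`, `da`, `estimate_c1`,
#'   `estimate_c2`, `p_c2`.
#' @examples
#' discriminate_gain_vs_ri()
#' @export
discriminate_gain_vs_ri <- function(true_reward = 7.5,
                                    prior_mean_c1 = 6.25,
                                    prior_mean_c2 = 8.75,
                                    encoding_precision = 1,
                                    prior_precision = 1,
                                    beta_low = 1, beta_high = 10,
                                    decode_boost = 10) {
  check_pos(encoding_precision, "encoding_precision")
  check_pos(prior_precision, "prior_precision")
  check_pos(decode_boost, "decode_boost")
  est <- function(prior_mean, lambda_est) {
    posterior(gaussian_belief(prior_mean, prior_precision),
              true_reward, lambda_est)$mean
  }
  p_c2 <- function(e1, e2, beta) softmax_probabilities(c(e1, e2), beta)[2]

  e1 <- est(prior_mean_c1, encoding_precision)
  e2 <- est(prior_mean_c2, encoding_precision)
  e1_hi <- est(prior_mean_c1, encoding_precision * decode_boost)
  e2_hi <- est(prior_mean_c2, encoding_precision * decode_boost)

  tibble::tibble(
    hypothesis = rep(c("gain_control", "rational_inattention"), each = 2),
    da = rep(c("low", "high"), times = 2),
    estimate_c1 = c(e1, e1, e1, e1_hi),
    estimate_c2 = c(e2, e2, e2, e2_hi),
    p_c2 = c(p_c2(e1, e2, beta_low), p_c2(e1, e2, beta_high),
             p_c2(e1, e2, beta_low), p_c2(e1_hi, e2_hi, beta_low))
  )
}
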