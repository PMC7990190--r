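#' Discounting-free value of an intertemporal option
#'
#' Average-reward-rate model of intertemporal choice: the value of choosing
#' option c is its reward divided by the *perceived* total trial duration,
#'
#'   v_c = r_c / (D + w),
#'
#' where D is the pre-reward delay and w the subjective estimate of the
#' post-reward delay (buffer). No temporal discounting is involved; apparent
#' impulsivity arises when w underestimates the true buffer.
#'
#' @param reward Strictly positive reward r_c.
#' @param pre_delay Non-negative pre-reward delay D, seconds.
#' @param w_post Non-negative subjective post-reward delay, seconds.
#' @return Value in reward per second.
#' @examples
#' value_discount_free(6, 2, 1) # 2
#' @export
value_discount_free <- function(reward, pre_delay, w_post) {
  check_pos(reward, "reward")
  check_nonneg(pre_delay, "pre_delay")
  check_nonneg(w_post, "w_post")
  if (any(pre_delay + w_post == 0)) {
    stop("`pre_delay + w_post` must be positive.", call. = FALSE)
  }
  reward / (pre_delay + w_post)
}

#' Hyperbolic-discounting value
#'
#' The one-parameter hyperbolic model v_c = r_c / (1 + k D). Order-equivalent
#' to [value_discount_free()] with w = 1/k: for any pair of options the two
#' models prefer the same one, so choice data alone cannot separate them.
#'
#' @param reward Strictly positive reward.
#' @param pre_delay Non-negative delay D, seconds.
#' @param k Strictly positive discount rate, per second.
#' @return Discounted value.
#' @export
value_hyperbolic <- function(reward, pre_delay, k) {
  check_pos(reward, "reward")
  check_nonneg(pre_delay, "pre_delay")
  check_pos(k, "k")
  reward / (1 + k * pre_delay)
}

#' Pacemaker period across controllability conditions
#'
#' Controllability gates whether average reward buys precision: the incentive
#' is R = contingent_rate / free_rate, so freely delivered rewards dilute the
#' value of attending to the timing task. lambda* follows from the attentional
#' problem, the clock gain realizes it at a reference duration, and the
#' pacemaker period is 1/eta. The period lengthens (clock slows) as free
#' reward rises and shortens as contingent reward rises; scaling both rates
#' together changes nothing.
#'
#' @param free_rates Strictly positive free (non-contingent) reward rates.
#' @param contingent_rates Non-negative performance-contingent reward rates.
#' @param info_cost kappa, per second.
#' @param prior_precision lambda0 of the attentional problem.
#' @param reference_duration Duration (seconds) at which the gain realizes
#'   lambda*; default 25, the switch point of the classic free-operant
#'   timing task.
#' @param l Subjective precision.
#' @return A tibble with columns `free_rate`, `contingent_rate`,
#'   `pacemaker_period`.
#' @examples
#' controllability_clock_sim(c(0.01, 0.02), 0.01)
#' @export
controllability_clock_sim <- function(free_rates, contingent_rates,
                                      info_cost = 0.1, prior_precision = 1,
                                      reference_duration = 25, l = 1) {
  check_pos(free_rates, "free_rates")
  check_nonneg(contingent_rates, "contingent_rates")
  tidyr::expand_grid(free_rate = free_rates,
                     contingent_rate = contingent_rates) |>
    dplyr::mutate(
      pacemaker_period = purrr::map2_dbl(
        .data$free_rate, .data$contingent_rate,
        function(fr, cr) {
          R <- incentive_from_context(free_reward_rate = fr,
                                      contingent_reward_rate = cr)
          lam <- optimal_precision(attention_problem(R, info_cost, prior_precision))
          1 / clock_gain_from_precision(lam, reference_duration, l)
        }
      )
    )
}

#' Subjective estimate of a post-reward delay
#'
#' Before reward the task is controllable and the clock runs at the gain
#' bought by `R_pre`; after reward nothing remains controllable, the
#' incentive drops to `R_post`, and the clock slows. Subjective time for the
#' buffer accumulates at the post-reward gain but is read out against the
#' pre-reward scale:
#'
#'   w_post = (buffer + 1)^(eta_post / eta_pre) - 1,
#'
#' so whenever R_post < R_pre the post-reward delay is underestimated
#' (w_post < buffer), with equality when the incentives match.
#'
#' @param buffer Non-negative true post-reward delay(s), seconds.
#' @param R_pre Incentive during the pre-reward delay.
#' @param R_post Incentive during the post-reward delay.
#' @param info_cost kappa, per second.
#' @param prior_precision lambda0 of the attentional problem.
#' @param reference_duration Reference for the clock gains (cancels in the
#'   gain ratio when shared, as here).
#' @param l Subjective precision.
#' @return A tibble with columns `buffer_s` and `w_post_s`.
#' @examples
#' post_reward_estimate(c(1, 2, 3, 4, 5, 10))
#' @export
post_reward_estimate <- function(buffer, R_pre = 1, R_post = 0.7,
                                 info_cost = 0.1, prior_precision = 1,
                                 reference_duration = 3, l = 1) {
  check_nonneg(buffer, "buffer")
  check_nonneg(R_pre, "R_pre")
  check_nonneg(R_post, "R_post")
  gain_for <- function(R) {
    lam <- optimal_precision(attention_problem(R, info_cost, prior_precision))
    clock_gain_from_precision(lam, reference_duration, l)
  }
  ratio <- gain_for(R_post) / gain_for(R_pre)
  tibble::tibble(buffer_s = buffer, w_post_s = (buffer + 1)^ratio - 1)
}

#' Perceived total durations in the standard intertemporal task
#'
#' In the fixed-length task (pre-reward delay plus buffer held constant) the
#' smaller/sooner option carries the longer buffer. A slower post-reward
#' clock therefore shrinks the perceived total of the smaller/sooner option
#' more than the larger/later option's, lowering apparent impulsivity.
#'
#' @param pre_delays Pre-reward delays of the options, seconds.
#' @param total_duration Fixed trial duration, seconds.
#' @inheritParams post_reward_estimate
#' @return A tibble with `pre_delay_s`, `buffer_s`, `w_post_s`,
#'   `perceived_total_s`.
#' @export
perceived_trial_durations <- function(pre_delays, total_duration = 6,
                                      R_pre = 1, R_post = 0.7,
                                      info_cost = 0.1) {
  check_pos(pre_delays, "pre_delays")
  if (any(pre_delays > total_duration)) {
    stop("`pre_delays` cannot exceed `total_duration`.", call. = FALSE)
  }
  buffers <- total_duration - pre_delays
  est <- post_reward_estimate(buffers, R_pre, R_post, info_cost)
  tibble::tibble(pre_delay_s = pre_delays, buffer_s = buffers,
                 w_post_s = est$w_post_s,
                 perceived_total_s = pre_delays + est$w_post_s)
}
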