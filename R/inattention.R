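#' Attentional optimization problem
#'
#' Bundles the three quantities that define how much precision a rational
#' agent should buy: the reward incentive R (subjective reward units, reported
#' by tonic dopamine), the unit cost of information kappa (reward units per
#' nat), and the prior precision lambda0 of the context.
#'
#' @param reward_incentive Non-negative R.
#' @param info_cost Strictly positive kappa.
#' @param prior_precision Strictly positive lambda0.
#' @return An object of class `attention_problem`.
#' @examples
#' attention_problem(1, 0.5, 0.5)
#' @export
attention_problem <- function(reward_incentive, info_cost, prior_precision) {
  check_nonneg(reward_incentive, "reward_incentive")
  check_pos(info_cost, "info_cost")
  check_pos(prior_precision, "prior_precision")
  structure(list(reward_incentive = as.numeric(reward_incentive),
                 info_cost = as.numeric(info_cost),
                 prior_precision = as.numeric(prior_precision)),
            class = "attention_problem")
}

#' @export
print.attention_problem <- function(x, ...) {
  cat(sprintf("<attention_problem> R = %g, kappa = %g, lambda0 = %g (lambda* = %g)\n",
              x$reward_incentive, x$info_cost, x$prior_precision,
              optimal_precision(x)))
  invisible(x)
}

#' Mutual information between source and encoded signal
#'
#' The expected reduction in uncertainty about the source due to observing
#' the signal, in nats:
#'
#'   I(mu; m) = 1/2 * log(1 + lambda / lambda0),
#'
#' the difference between the Gaussian entropies of the prior (precision
#' lambda0) and the posterior (precision lambda0 + lambda). Zero iff the
#' likelihood precision is zero, and monotone increasing in it.
#'
#' @param lambda_like Non-negative likelihood precision, vectorized.
#' @param lambda_prior Strictly positive prior precision.
#' @return Mutual information in nats.
#' @examples
#' mutual_information(1, 1) # log(2) / 2
#' @export
mutual_information <- function(lambda_like, lambda_prior) {
  check_nonneg(lambda_like, "lambda_like")
  check_pos(lambda_prior, "lambda_prior")
  0.5 * log1p(lambda_like / lambda_prior)
}

#' Reward-weighted error plus information cost
#'
#' The objective a rationally inattentive (calibrated) agent minimizes over
#' its likelihood precision lambda:
#'
#'   R / (lambda + lambda0) + kappa * 1/2 * log(1 + lambda / lambda0).
#'
#' The first term is the reward-weighted marginal decoding error; the second
#' the attentional (mutual-information) cost. The objective is unimodal in
#' lambda, so a bounded 1-D minimizer recovers [optimal_precision()].
#'
#' @param lambda_like Non-negative candidate precision(s).
#' @param problem An [attention_problem()].
#' @return Objective value(s), in reward units.
#' @export
attentional_objective <- function(lambda_like, problem) {
  stopifnot(inherits(problem, "attention_problem"))
  check_nonneg(lambda_like, "lambda_like")
  problem$reward_incentive / (lambda_like + problem$prior_precision) +
    problem$info_cost * mutual_information(lambda_like, problem$prior_precision)
}

#' Optimal likelihood precision
#'
#' Closed-form solution of the attentional optimization problem:
#'
#'   lambda* = max(0, 2 * R / kappa - lambda0).
#'
#' Piecewise linear in R: below the threshold 2R/kappa <= lambda0 the prior
#' alone already meets the incentivized posterior precision and the agent
#' attends not at all; above it, the agent tops posterior precision up to
#' 2R/kappa, so lambda* rises with slope 2/kappa. lambda* is non-increasing
#' in both kappa and lambda0.
#'
#' @param problem An [attention_problem()].
#' @return Non-negative optimal precision.
#' @examples
#' optimal_precision(attention_problem(0.1, 0.5, 0.5)) # 0: flat segment
#' optimal_precision(attention_problem(1, 0.5, 0.5))   # 3.5
#' @export
optimal_precision <- function(problem) {
  stopifnot(inherits(problem, "attention_problem"))
  max(0, 2 * problem$reward_incentive / problem$info_cost -
        problem$prior_precision)
}

#' Piecewise-linear precision-incentive curve
#'
#' Evaluates lambda* over a grid of reward incentives, returning a tidy table
#' suitable for plotting the piecewise-linear relationship (kink at
#' R = kappa * lambda0 / 2, slope 2 / kappa above it).
#'
#' @param R_grid Non-negative, ascending grid of reward incentives.
#' @param info_cost,prior_precision Problem parameters.
#' @return A tibble with columns `R` and `lambda_star`.
#' @export
precision_incentive_curve <- function(R_grid, info_cost = 0.5,
                                      prior_precision = 0.5) {
  check_nonneg(R_grid, "R_grid")
  tibble::tibble(
    R = R_grid,
    lambda_star = purrr::map_dbl(
      R_grid,
      ~ optimal_precision(attention_problem(.x, info_cost, prior_precision))
    )
  )
}

#' Reward incentive implied by a behavioral context
#'
#' Tonic dopamine is taken to report the context's average reward, which sets
#' the incentive R of the attentional problem. Two mappings are supported:
#'
#' * **Dopamine mapping** (default, when no reward-rate structure is given):
#'   R equals the dopamine level, i.e. average reward is read straight off
#'   the tonic signal.
#' * **Controllability (ratio) mapping**: when rewards split into a freely
#'   delivered (non-contingent) rate and a performance-contingent rate, the
#'   incentive to attend falls as free reward rises; R =
#'   `contingent_reward_rate / free_reward_rate`, inverse in the free rate and
#'   proportional to the contingent rate.
#'
#' @param dopamine_level Non-negative tonic DA level (arbitrary units).
#' @param free_reward_rate Optional strictly positive non-contingent reward
#'   rate (rewards per unit time).
#' @param contingent_reward_rate Optional non-negative contingent reward rate.
#' @return Non-negative incentive R.
#' @examples
#' incentive_from_context(dopamine_level = 0.9) # 0.9
#' incentive_from_context(free_reward_rate = 0.02, contingent_reward_rate = 0.01)
#' @export
incentive_from_context <- function(dopamine_level = NULL,
                                   free_reward_rate = NULL,
                                   contingent_reward_rate = NULL) {
  if (is.null(free_reward_rate) && is.null(contingent_reward_rate)) {
    if (is.null(dopamine_level)) {
      stop("Supply either `dopamine_level` or both reward rates.", call. = FALSE)
    }
    check_nonneg(dopamine_level, "dopamine_level")
    return(as.numeric(dopamine_level))
  }
  if (is.null(free_reward_rate) || is.null(contingent_reward_rate)) {
    stop("The controllability mapping needs both `free_reward_rate` and `contingent_reward_rate`.",
         call. = FALSE)
  }
  if (any(!is.finite(free_reward_rate)) || any(free_reward_rate <= 0)) {
    stop("`free_reward_rate` must be strictly positive under the ratio mapping; use the dopamine mapping instead.",
         call. = FALSE)
  }
  check_nonneg(contingent_reward_rate, "contingent_reward_rate")
  contingent_reward_rate / free_reward_rate
}

#' Decoding error across incentives when true precision is bounded
#'
#' The closed-form lambda* describes the precision the agent *believes* it
#' buys. If the encoding machinery saturates at some ceiling `lambda_max`,
#' further incentive raises the estimated precision without raising the true
#' one, miscalibrating the channel (c > 1) and eventually *worsening*
#' performance: decoding error over an incentive grid is U-shaped (an
#' inverted U in performance). With an unbounded channel the error is
#' monotone non-increasing in R.
#'
#' @param R_grid Ascending non-negative grid of reward incentives.
#' @param info_cost,prior_precision Attention-problem parameters.
#' @param lambda_max Strictly positive precision ceiling, or `Inf` for an
#'   unbounded channel.
#' @return A tibble with columns `R`, `lambda_est`, `lambda_true`, `error`.
#' @examples
#' curve <- bounded_performance_curve(seq(0, 5, 0.25), 0.5, 0.5, lambda_max = 4)
#' curve$R[which.min(curve$error)] # interior minimum
#' @export
bounded_performance_curve <- function(R_grid, info_cost, prior_precision,
                                      lambda_max = Inf) {
  check_nonneg(R_grid, "R_grid")
  if (is.unsorted(R_grid)) stop("`R_grid` must be ascending.", call. = FALSE)
  if (is.na(lambda_max) || lambda_max <= 0) {
    stop("`lambda_max` must be strictly positive (possibly Inf).", call. = FALSE)
  }
  purrr::map_dfr(R_grid, function(R) {
    lam_est <- optimal_precision(attention_problem(R, info_cost, prior_precision))
    lam_true <- min(lam_est, lambda_max)
    err <- marginal_error(miscalibrated_channel(lam_true, lam_est),
                          prior_precision)
    tibble::tibble(R = R, lambda_est = lam_est, lambda_true = lam_true,
                   error = err)
  })
}
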