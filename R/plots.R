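#' Plot an experiment result
#'
#' Dispatches on the experiment that produced the result and draws the
#' field-standard view: the piecewise-linear precision-incentive curve,
#' win-shift against dopamine by risk, relative accuracy against dopamine,
#' reproduced against presented duration by dopamine level, pacemaker period
#' against reward rates, estimated against true post-reward delay, and choice
#' probabilities for the prediction experiments.
#'
#' @param object An `experiment_result` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(run_experiment("central_tendency"))
#' @export
autoplot.experiment_result <- function(object, ...) {
  name <- attr(object, "experiment")
  d <- tidy(object)
  switch(
    name,
    lambda_star_curve = ggplot2::ggplot(d, ggplot2::aes(.data$R, .data$lambda_star)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "reward incentive R", y = expression(lambda^"*")),
    bandit_winshift = ggplot2::ggplot(d, ggplot2::aes(.data$da, .data$winshift,
                                                      colour = .data$risk)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "tonic DA", y = "win-shift probability"),
    feedback_asymmetry = ggplot2::ggplot(d, ggplot2::aes(.data$da, .data$relative_accuracy)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "tonic DA", y = "relative accuracy (pos - neg)"),
    central_tendency = duration_plot(d),
    clock_speed = duration_plot(d),
    controllability = ggplot2::ggplot(d, ggplot2::aes(.data$free_rate, .data$pacemaker_period,
                                                      colour = factor(.data$contingent_rate))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "free reward rate (1/s)", y = "pacemaker period (s)",
                    colour = "contingent rate"),
    post_reward_delay = ggplot2::ggplot(d, ggplot2::aes(.data$buffer_s, .data$w_post_s)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "true buffer (s)", y = "estimated post-reward delay (s)"),
    transfer_choice = ggplot2::ggplot(
      tidyr::pivot_longer(d, c("p_high", "p_low"),
                          names_to = "context", values_to = "p"),
      ggplot2::aes(.data$pair, .data$p, fill = .data$context)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "transfer pair", y = "choice probability"),
    rpe_magnitude = ggplot2::ggplot(d, ggplot2::aes(factor(.data$outcome), .data$rpe,
                                                    fill = .data$controllability)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(x = "outcome", y = "estimated RPE"),
    gain_vs_inattention = ggplot2::ggplot(
      d, ggplot2::aes(factor(.data$da, levels = c("low", "high")), .data$p_c2,
                      group = .data$hypothesis, colour = .data$hypothesis)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "DA at test", y = "p(C2)"),
    inverted_u = ggplot2::ggplot(d, ggplot2::aes(.data$R, .data$error)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "reward incentive R", y = "marginal decoding error"),
    stop("No plot registered for experiment ", name, call. = FALSE)
  )
}

duration_plot <- function(d) {
  ggplot2::ggplot(d, ggplot2::aes(.data$duration_s, .data$reproduction_s,
                                  colour = factor(.data$da))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "presented duration (s)", y = "reproduced duration (s)",
                  colour = "DA")
}

#' Marginal error as a function of miscalibration
#'
#' Error profile over the miscalibration factor c for a fixed true precision
#' and prior precision; the minimum always sits at the calibrated channel
#' c = 1.
#'
#' @param lambda_true,lambda_prior Channel and prior precisions.
#' @param c_grid Grid of factors (default [miscalibration_grid()]).
#' @return A ggplot object.
#' @export
plot_miscalibration_error <- function(lambda_true = 1, lambda_prior = 1,
                                      c_grid = miscalibration_grid()) {
  d <- tibble::tibble(
    c = c_grid,
    error = purrr::map_dbl(
      c_grid,
      ~ marginal_error(miscalibrated_channel(lambda_true, .x * lambda_true),
                       lambda_prior))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$c, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "miscalibration factor c", y = "marginal error")
}
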