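#' Weight given to the likelihood mean
#'
#' In the conjugate Gaussian model the posterior mean is a precision-weighted
#' average of the encoded signal and the prior mean. With estimated precision
#' c * lambda (a possibly miscalibrated decoding stage), the signal weight is
#'
#'   w = c * lambda / (c * lambda + lambda0).
#'
#' w is bounded by 0 and 1 and increases with both the likelihood precision
#' and the miscalibration factor c.
#'
#' @param lambda_like Non-negative likelihood (encoding) precision, vectorized.
#' @param lambda_prior Strictly positive prior precision.
#' @param c Positive miscalibration factor; 1 (the default) is calibrated.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' likelihood_weight(1, 1)       # 0.5
#' likelihood_weight(1, 1, c = 2) # 2/3: overestimated precision leans on the signal
#' @export
likelihood_weight <- function(lambda_like, lambda_prior, c = 1) {
  check_nonneg(lambda_like, "lambda_like")
  check_pos(lambda_prior, "lambda_prior")
  check_pos(c, "c")
  c * lambda_like / (c * lambda_like + lambda_prior)
}

#' Posterior belief after observing an encoded signal
#'
#' Conjugate Gaussian update: the posterior mean is
#' `w * signal + (1 - w) * prior$mean` with `w = likelihood_weight(lambda_est,
#' prior$precision)`, and the posterior precision is the sum
#' `prior$precision + lambda_est`. With `lambda_est = 0` the signal carries no
#' information and the posterior equals the prior.
#'
#' The precision used here is the *decoding-stage* (estimated) precision; if
#' it differs from the true encoding precision, the update is miscalibrated
#' (see [marginal_error()]).
#'
#' @param prior A [gaussian_belief()] with positive precision.
#' @param signal The stored signal value m.
#' @param lambda_est Non-negative precision assumed at decoding.
#' @return A [gaussian_belief()]; its mean lies between the prior mean and the
#'   signal.
#' @examples
#' posterior(gaussian_belief(0, 1), signal = 2, lambda_est = 1)$mean # 1
#' @export
posterior <- function(prior, signal, lambda_est) {
  stopifnot(inherits(prior, "gaussian_belief"))
  check_pos(prior$precision, "prior$precision")
  check_nonneg(lambda_est, "lambda_est")
  w <- likelihood_weight(lambda_est, prior$precision)
  gaussian_belief(mean = w * signal + (1 - w) * prior$mean,
                  precision = prior$precision + lambda_est)
}

#' Expected squared error for a particular source
#'
#' The agent's expected response variance conditional on the latent stimulus
#' mu (quadratic loss, averaging over encoding noise only):
#'
#'   E\[(mu - muhat(m))^2 | mu\] = w^2 / lambda + (1 - w)^2 * (mu - mu0)^2,
#'
#' where lambda is the *true* encoding precision and w is formed from the
#' *estimated* precision. When the source sits at the prior mean only the
#' variance term remains; away from it the prior pulls the estimate and adds a
#' squared bias.
#'
#' @param source Latent stimulus value mu.
#' @param prior A [gaussian_belief()] with positive precision.
#' @param channel A [miscalibrated_channel()] with positive true precision.
#' @return Non-negative expected squared error.
#' @export
conditional_error <- function(source, prior, channel) {
  stopifnot(inherits(prior, "gaussian_belief"),
            inherits(channel, "miscalibrated_channel"))
  check_pos(prior$precision, "prior$precision")
  if (channel$lambda_true <= 0) {
    stop("`lambda_true` must be positive: a zero-precision channel has infinite response variance.",
         call. = FALSE)
  }
  w <- likelihood_weight(channel$lambda_est, prior$precision)
  w^2 / channel$lambda_true + (1 - w)^2 * (source - prior$mean)^2
}

#' Marginal (source-averaged) decoding error
#'
#' Averaging the conditional error over sources mu ~ N(mu0, 1/lambda0) gives
#' the overall response variance
#'
#'   w^2 / lambda + (1 - w)^2 / lambda0,
#'
#' which collapses to 1 / (lambda + lambda0) exactly when the channel is
#' calibrated (estimated = true precision). Any miscalibration c != 1
#' strictly increases it.
#'
#' @param channel A [miscalibrated_channel()]. `lambda_true` must be positive
#'   unless the estimated precision is also 0 (then the posterior is the prior
#'   and the error is `1 / lambda_prior`).
#' @param lambda_prior Strictly positive prior precision.
#' @return Non-negative marginal error.
#' @examples
#' marginal_error(miscalibrated_channel(1, 1), 1)  # 0.5 = 1 / (1 + 1)
#' marginal_error(miscalibrated_channel(1, 2), 1)  # 5/9 > 0.5
#' @export
marginal_error <- function(channel, lambda_prior) {
  stopifnot(inherits(channel, "miscalibrated_channel"))
  check_pos(lambda_prior, "lambda_prior")
  w <- likelihood_weight(channel$lambda_est, lambda_prior)
  if (w == 0) return(1 / lambda_prior)
  if (channel$lambda_true <= 0) {
    stop("`lambda_true` must be positive when the decoding weight is non-zero.",
         call. = FALSE)
  }
  w^2 / channel$lambda_true + (1 - w)^2 / lambda_prior
}

#' Error-minimizing miscalibration factor by grid search
#'
#' Evaluates the marginal decoding error over a grid of miscalibration
#' factors c (estimated precision = c * true precision) and returns the grid
#' argmin. For any true precision and prior precision the minimizer is the
#' calibrated channel, c = 1; the function exists to verify that fact
#' numerically and to expose the error profile.
#'
#' @param lambda_true Strictly positive true precision.
#' @param lambda_prior Strictly positive prior precision.
#' @param c_grid Positive grid of candidate factors. The default is a
#'   geometric grid on `[0.05, 10]` with the value 1 inserted; a sensible grid
#'   spans at least `[0.1, 10]` and contains 1.
#' @return The factor c minimizing the marginal error over the grid.
#' @examples
#' optimal_miscalibration(1, 1) # 1
#' @export
optimal_miscalibration <- function(lambda_true, lambda_prior,
                                   c_grid = miscalibration_grid()) {
  check_pos(lambda_true, "lambda_true")
  check_pos(lambda_prior, "lambda_prior")
  if (length(c_grid) == 0) stop("`c_grid` must be non-empty.", call. = FALSE)
  check_pos(c_grid, "c_grid")
  errs <- vapply(c_grid, function(cc) {
    marginal_error(miscalibrated_channel(lambda_true, cc * lambda_true),
                   lambda_prior)
  }, numeric(1))
  c_grid[which.min(errs)]
}

#' Default geometric grid of miscalibration factors
#'
#' @param lower,upper Grid range (positive).
#' @param n Number of geometric points before 1 is inserted.
#' @return Sorted positive grid containing exactly 1.
#' @export
miscalibration_grid <- function(lower = 0.05, upper = 10, n = 200) {
  check_pos(lower, "lower")
  check_pos(upper, "upper")
  sort(unique(c(1, exp(seq(log(lower), log(upper), length.out = n)))))
}

# argument checks shared across the package
check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive.", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(is.na(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative.", name), call. = FALSE)
  }
  invisible(x)
}
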