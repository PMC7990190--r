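#' Gaussian belief over a scalar stimulus
#'
#' A mean/precision pair describing a Gaussian distribution over a scalar
#' stimulus (an interval duration in seconds, or a reward magnitude). The same
#' structure represents priors, likelihoods, and posteriors. Precision is the
#' inverse variance; a belief used as a prior for inference must have strictly
#' positive precision, while a likelihood may have precision zero (an
#' uninformative, "no signal" channel).
#'
#' @param mean Scalar mean, in stimulus units.
#' @param precision Scalar inverse variance (stimulus units^-2); must be
#'   non-negative.
#'
#' @return An object of class `gaussian_belief`: a list with elements `mean`
#'   and `precision`.
#' @examples
#' prior <- gaussian_belief(14.5, 1 / 5.2^2)
#' belief_entropy(prior)
#' @export
gaussian_belief <- function(mean, precision) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  stopifnot(is.numeric(precision), length(precision) == 1L)
  if (is.na(precision) || precision < 0) {
    stop("`precision` must be a non-negative number.", call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), precision = as.numeric(precision)),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> mean = %g, precision = %g (sd = %g)\n",
              x$mean, x$precision,
              if (x$precision > 0) 1 / sqrt(x$precision) else Inf))
  invisible(x)
}

#' Differential entropy of a Gaussian belief
#'
#' Computes 1/2 * log(2 * pi * e / precision), in nats. Finite whenever the
#' precision is strictly positive. The mutual-information attention cost is the
#' difference between prior and posterior entropies (see
#' [mutual_information()]).
#'
#' @param belief A [gaussian_belief()].
#' @return Entropy in nats; `Inf` for a zero-precision belief.
#' @export
belief_entropy <- function(belief) {
  stopifnot(inherits(belief, "gaussian_belief"))
  if (belief$precision == 0) return(Inf)
  0.5 * log(2 * pi * exp(1) / belief$precision)
}

#' Encoding channel with separate true and estimated precision
#'
#' The noisy encoding stage stores a signal m ~ N(mu, 1/lambda_true). At the
#' decoding stage the agent may assume a different precision `lambda_est`
#' (e.g. after an acute dopamine manipulation), giving a miscalibration factor
#' c = lambda_est / lambda_true. The factor is derived on demand, never stored,
#' so a channel can not carry an inconsistent (lambda, lambda', c) triple.
#'
#' @param lambda_true Non-negative true encoding precision.
#' @param lambda_est Non-negative estimated (decoding) precision. Defaults to
#'   `lambda_true`, i.e. a calibrated channel.
#' @return An object of class `miscalibrated_channel`.
#' @examples
#' ch <- miscalibrated_channel(1, 2)
#' miscalibration_factor(ch) # 2: precision is overestimated
#' @export
miscalibrated_channel <- function(lambda_true, lambda_est = lambda_true) {
  stopifnot(is.numeric(lambda_true), length(lambda_true) == 1L,
            is.numeric(lambda_est), length(lambda_est) == 1L)
  if (is.na(lambda_true) || lambda_true < 0) {
    stop("`lambda_true` must be non-negative.", call. = FALSE)
  }
  if (is.na(lambda_est) || lambda_est < 0) {
    stop("`lambda_est` must be non-negative.", call. = FALSE)
  }
  structure(list(lambda_true = as.numeric(lambda_true),
                 lambda_est = as.numeric(lambda_est)),
            class = "miscalibrated_channel")
}

#' @export
print.miscalibrated_channel <- function(x, ...) {
  c_fac <- if (x$lambda_true > 0) x$lambda_est / x$lambda_true else NA_real_
  cat(sprintf("<miscalibrated_channel> lambda_true = %g, lambda_est = %g, c = %g\n",
              x$lambda_true, x$lambda_est, c_fac))
  invisible(x)
}

#' Miscalibration factor of a channel
#'
#' The ratio c = lambda_est / lambda_true. c < 1 means precision is
#' underestimated; c > 1, overestimated; c = 1 is the calibrated (and, for
#' marginal decoding error, optimal) case. Defined only for channels with
#' strictly positive true precision.
#'
#' @param channel A [miscalibrated_channel()].
#' @return The scalar factor c > 0.
#' @export
miscalibration_factor <- function(channel) {
  stopifnot(inherits(channel, "miscalibrated_channel"))
  if (channel$lambda_true <= 0) {
    stop("Miscalibration factor is undefined when `lambda_true` is 0.",
         call. = FALSE)
  }
  channel$lambda_est / channel$lambda_true
}

#' Draw encoded signals from a channel
#'
#' Samples stored signals m ~ N(source, 1/lambda_true) for Monte-Carlo checks
#' of the closed-form error expressions.
#'
#' @param n Number of draws.
#' @param source The latent stimulus value generating the signal.
#' @param channel A [miscalibrated_channel()] with positive true precision.
#' @return Numeric vector of length `n`.
#' @export
encode_signal <- function(n, source, channel) {
  stopifnot(inherits(channel, "miscalibrated_channel"))
  if (channel$lambda_true <= 0) {
    stop("Cannot sample signals from a zero-precision channel.", call. = FALSE)
  }
  stats::rnorm(n, mean = source, sd = 1 / sqrt(channel$lambda_true))
}
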