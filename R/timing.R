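#' Objective-subjective time mapping
#'
#' The internal clock maps objective duration mu (seconds) to subjective time
#' m = eta * log(mu + 1), with fixed subjective-space encoding precision l.
#' The logarithmic form makes decoded reproductions obey Weber-like scaling
#' (response SD roughly proportional to duration); the gain eta is the clock
#' speed — larger eta compresses temporal receptive fields against objective
#' time, i.e. a faster clock — and its inverse is the pacemaker period.
#'
#' @param clock_gain Strictly positive gain eta (subjective units per
#'   log-second).
#' @param subjective_precision Strictly positive precision l of the encoding
#'   noise in subjective units; default 1.
#' @return An object of class `time_mapping`.
#' @examples
#' tm <- time_mapping(clock_gain = 2)
#' from_subjective(to_subjective(7, tm), tm) # 7
#' @export
time_mapping <- function(clock_gain, subjective_precision = 1) {
  check_pos(clock_gain, "clock_gain")
  check_pos(subjective_precision, "subjective_precision")
  structure(list(clock_gain = as.numeric(clock_gain),
                 subjective_precision = as.numeric(subjective_precision)),
            class = "time_mapping")
}

#' @export
print.time_mapping <- function(x, ...) {
  cat(sprintf("<time_mapping> eta = %g (pacemaker period %g), l = %g\n",
              x$clock_gain, 1 / x$clock_gain, x$subjective_precision))
  invisible(x)
}

#' Convert between objective and subjective time
#'
#' `to_subjective()` applies m = eta * log(mu + 1); `from_subjective()` its
#' inverse mu = exp(m / eta) - 1. The two are exact inverses; m(0) = 0 and the
#' mapping is strictly increasing.
#'
#' @param duration Non-negative objective duration(s), seconds.
#' @param m Non-negative subjective time(s).
#' @param mapping A [time_mapping()].
#' @return Numeric vector of converted times.
#' @export
to_subjective <- function(duration, mapping) {
  stopifnot(inherits(mapping, "time_mapping"))
  check_nonneg(duration, "duration")
  mapping$clock_gain * log1p(duration)
}

#' @rdname to_subjective
#' @export
from_subjective <- function(m, mapping) {
  stopifnot(inherits(mapping, "time_mapping"))
  check_nonneg(m, "m")
  expm1(m / mapping$clock_gain)
}

#' Clock gain achieving a target objective-time precision
#'
#' Precision in the timing model is bought by rescaling the clock: under the
#' logarithmic mapping, subjective-space noise of precision l corresponds (by
#' the delta method) to objective-time precision l * eta^2 / (mu + 1)^2 at
#' duration mu. Given the precision lambda* the attentional problem
#' prescribes, the gain that delivers it at a reference duration is
#'
#'   eta = (reference + 1) * sqrt(max(lambda*, lambda_floor) / l).
#'
#' A small positive floor keeps the clock running even when lambda* = 0 — an
#' agent never withdraws attention completely, and a stopped clock is
#' degenerate.
#'
#' @param lambda_star Non-negative objective-time precision target.
#' @param reference_duration Strictly positive reference duration in seconds
#'   (or 0 for the identity normalization eta = sqrt(lambda*/l)).
#' @param l Strictly positive subjective precision.
#' @param lambda_floor Small positive floor applied to `lambda_star`.
#' @return Strictly positive gain eta.
#' @examples
#' clock_gain_from_precision(1, reference_duration = 0, l = 1) # 1
#' @export
clock_gain_from_precision <- function(lambda_star, reference_duration, l = 1,
                                      lambda_floor = 1e-3) {
  check_nonneg(lambda_star, "lambda_star")
  if (!is.finite(reference_duration) || reference_duration < 0) {
    stop("`reference_duration` must be a non-negative number.", call. = FALSE)
  }
  check_pos(l, "l")
  check_pos(lambda_floor, "lambda_floor")
  (reference_duration + 1) * sqrt(max(lambda_star, lambda_floor) / l)
}

#' Encode and reproduce an interval, possibly at a different clock speed
#'
#' Deterministic (expected-encoding) reproduction pipeline: the duration is
#' encoded at gain `eta_encode` to the expected subjective time
#' m = eta_encode * log(mu + 1); a subjective-space Bayesian update against
#' `subjective_prior` with likelihood precision `l` yields the posterior mean;
#' decoding inverts the mapping at gain `eta_decode`. With an uninformative
#' prior the reproduction is (mu + 1)^(eta_encode / eta_decode) - 1: a faster
#' decoding clock (eta_decode > eta_encode, e.g. acute dopamine elevation)
#' underproduces, a slower one overproduces.
#'
#' @param duration Strictly positive duration in seconds.
#' @param eta_encode,eta_decode Strictly positive encoding/decoding gains.
#' @param subjective_prior A [gaussian_belief()] in subjective units. Use
#'   precision 0 for an uninformative prior (the posterior is then the
#'   likelihood mean).
#' @param l Strictly positive subjective likelihood precision.
#' @return Reproduced duration, seconds.
#' @examples
#' flat <- gaussian_belief(0, 0)
#' reproduce_interval(7, 1, 1.2, flat) # about 4.66: underproduction
#' @export
reproduce_interval <- function(duration, eta_encode, eta_decode,
                               subjective_prior, l = 1) {
  check_pos(duration, "duration")
  check_pos(eta_encode, "eta_encode")
  check_pos(eta_decode, "eta_decode")
  check_pos(l, "l")
  stopifnot(inherits(subjective_prior, "gaussian_belief"))
  m_bar <- eta_encode * log1p(duration)
  if (subjective_prior$precision > 0) {
    m_hat <- posterior(subjective_prior, m_bar, l)$mean
  } else {
    m_hat <- m_bar
  }
  expm1(m_hat / eta_decode)
}

#' Objective prior mapped to subjective coordinates
#'
#' Transforms a prior stated in objective seconds into subjective units via
#' the delta method at the prior mean: subjective mean eta * log(mu0 + 1),
#' subjective precision lambda0 * (mu0 + 1)^2 / eta^2.
#'
#' @param prior A [gaussian_belief()] in objective seconds.
#' @param mapping A [time_mapping()].
#' @return A [gaussian_belief()] in subjective units.
#' @export
subjective_prior <- function(prior, mapping) {
  stopifnot(inherits(prior, "gaussian_belief"), inherits(mapping, "time_mapping"))
  gaussian_belief(
    mean = mapping$clock_gain * log1p(prior$mean),
    precision = prior$precision * (prior$mean + 1)^2 / mapping$clock_gain^2
  )
}

#' Central-tendency (interleaved reproduction) simulation
#'
#' Models reproduction of interleaved durations under different tonic
#' dopamine levels. Per DA level: the incentive R equals DA; lambda* comes
#' from the attentional problem with the condition's objective prior
#' precision; the clock gain realizes lambda* at the mean presented duration;
#' each duration is encoded and decoded at that same gain (no acute
#' manipulation), with the prior exerting a Bayesian pull in subjective
#' space. Low DA buys little precision, so reproductions migrate toward the
#' prior mean — short intervals are overproduced and long ones underproduced;
#' high DA yields near-veridical reproduction.
#'
#' The prior defaults to a Gaussian centred on the mid-duration with standard
#' deviation equal to the spread between the extreme durations divided by 2.5.
#'
#' @param durations Two or more presented durations, seconds.
#' @param dopamine_levels Strictly positive DA levels (one condition each).
#' @param info_cost Information cost kappa, per second.
#' @param prior Optional [gaussian_belief()] in objective seconds; default as
#'   described.
#' @param l Subjective likelihood precision.
#' @return A tibble with columns `duration_s`, `da`, `reproduction_s`.
#' @examples
#' central_tendency_sim(c(8, 21), c(0.2, 1))
#' @export
central_tendency_sim <- function(durations, dopamine_levels,
                                 info_cost = 0.05, prior = NULL, l = 1) {
  check_pos(durations, "durations")
  if (length(durations) < 2) stop("Need at least two durations.", call. = FALSE)
  check_pos(dopamine_levels, "dopamine_levels")
  if (is.null(prior)) {
    prior_sd <- (max(durations) - min(durations)) / 2.5
    prior <- gaussian_belief(mean(range(durations)), 1 / prior_sd^2)
  }
  stopifnot(inherits(prior, "gaussian_belief"))
  reference <- mean(durations)
  purrr::map_dfr(dopamine_levels, function(da) {
    R <- incentive_from_context(dopamine_level = da)
    lam_star <- optimal_precision(attention_problem(R, info_cost, prior$precision))
    eta <- clock_gain_from_precision(lam_star, reference, l)
    tm <- time_mapping(eta, l)
    sp <- subjective_prior(prior, tm)
    tibble::tibble(
      duration_s = durations,
      da = da,
      reproduction_s = purrr::map_dbl(
        durations, ~ reproduce_interval(.x, eta, eta, sp, l)
      )
    )
  })
}

#' Clock-speed (blocked reproduction) simulation
#'
#' Models acute dopamine manipulation at decoding: intervals are learned in
#' blocks (so no cross-duration prior operates) at baseline DA, then decoded
#' at each listed DA level. Encoding and decoding gains realize the
#' attentional precision bought at the respective DA, referenced to the
#' duration itself. Elevated decoding DA speeds the clock and underproduces;
#' lowered DA slows it and overproduces; baseline decoding is veridical.
#'
#' @param durations Strictly positive durations, seconds.
#' @param dopamine_levels Decoding-stage DA levels.
#' @param info_cost Information cost kappa, per second.
#' @param baseline_da DA level in force during encoding.
#' @param prior_precision Objective prior precision used in the attentional
#'   problem; near zero for the blocked design.
#' @param l Subjective likelihood precision.
#' @return A tibble with columns `duration_s`, `da`, `reproduction_s`.
#' @examples
#' clock_speed_sim(c(7, 17), c(0.8, 1, 1.2))
#' @export
clock_speed_sim <- function(durations, dopamine_levels, info_cost = 0.1,
                            baseline_da = 1, prior_precision = 1e-6, l = 1) {
  check_pos(durations, "durations")
  check_pos(dopamine_levels, "dopamine_levels")
  check_pos(baseline_da, "baseline_da")
  flat <- gaussian_belief(0, 0)
  gain_at <- function(da, duration) {
    lam <- optimal_precision(
      attention_problem(incentive_from_context(dopamine_level = da),
                        info_cost, prior_precision)
    )
    clock_gain_from_precision(lam, duration, l)
  }
  tidyr::expand_grid(duration_s = durations, da = dopamine_levels) |>
    dplyr::mutate(
      reproduction_s = purrr::map2_dbl(
        .data$duration_s, .data$da,
        function(mu, da) {
          reproduce_interval(mu,
                             eta_encode = gain_at(baseline_da, mu),
                             eta_decode = gain_at(da, mu),
                             subjective_prior = flat, l = l)
        }
      )
    )
}

#' Sample noisy interval reproductions
#'
#' Stochastic counterpart of [reproduce_interval()] used for variance
#' properties: subjective encodings are drawn m ~ N(eta * log(mu + 1), 1/l)
#' and decoded with an uninformative prior at the same gain. Under the
#' logarithmic mapping the SD of the decoded reproduction grows approximately
#' linearly with the duration (Weber-like scalar timing).
#'
#' @param n Number of draws per duration.
#' @param durations Strictly positive durations, seconds.
#' @param mapping A [time_mapping()].
#' @return A tibble with columns `duration_s` and `reproduction_s`.
#' @export
sample_reproductions <- function(n, durations, mapping) {
  stopifnot(inherits(mapping, "time_mapping"))
  check_pos(durations, "durations")
  purrr::map_dfr(durations, function(mu) {
    m <- stats::rnorm(n, mean = to_subjective(mu, mapping),
                      sd = 1 / sqrt(mapping$subjective_precision))
    tibble::tibble(duration_s = mu, reproduction_s = expm1(m / mapping$clock_gain))
  })
}
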