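# Independent Monte-Carlo and numerical oracles used across the suite.
# These deliberately avoid the closed-form code paths they check.

# Expected squared error for a fixed source, by sampling encodings and
# decoding each with the (possibly miscalibrated) estimated precision.
mc_conditional_error <- function(source, prior_mean, lambda_prior,
                                 lambda_true, lambda_est,
                                 n = 1e5, seed = 1) {
  set.seed(seed)
  m <- rnorm(n, source, 1 / sqrt(lambda_true))
  w <- lambda_est / (lambda_est + lambda_prior)
  mu_hat <- w * m + (1 - w) * prior_mean
  err <- (source - mu_hat)^2
  list(mean = mean(err), se = sd(err) / sqrt(n))
}

# Source-averaged squared error: sample sources from the prior, encode with
# the true precision, decode with the estimated precision.
mc_marginal_error <- function(prior_mean, lambda_prior, lambda_true,
                              lambda_est, n = 1e5, seed = 1) {
  set.seed(seed)
  mu <- rnorm(n, prior_mean, 1 / sqrt(lambda_prior))
  m <- rnorm(n, mu, 1 / sqrt(lambda_true))
  w <- lambda_est / (lambda_est + lambda_prior)
  mu_hat <- w * m + (1 - w) * prior_mean
  err <- (mu - mu_hat)^2
  list(mean = mean(err), se = sd(err) / sqrt(n))
}

# Bounded 1-D minimizer of the reward-weighted error + information cost,
# written out directly rather than through attentional_objective().
numeric_lambda_star <- function(R, kappa, lambda0, upper = 1e3) {
  f <- function(lam) R / (lam + lambda0) + kappa * 0.5 * log1p(lam / lambda0)
  opt <- optim(par = min(1, upper / 2), fn = f, method = "L-BFGS-B",
               lower = 0, upper = upper,
               control = list(factr = 1e1))
  opt$par
}
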