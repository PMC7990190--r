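#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment result
#'
#' Returns the result's tidy table as a plain tibble (condition columns plus
#' the simulated readout), dropping the result-class attributes.
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.experiment_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' One-row summary of an experiment result
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A one-row tibble with `experiment`, `n_rows`, `seed`, `version`.
#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(experiment = attr(x, "experiment"),
                 n_rows = nrow(x),
                 seed = attr(x, "seed"),
                 version = attr(x, "version"))
}

#' Tidy an attention problem
#'
#' One row per model term: the incentive, the information cost, the prior
#' precision, and the implied optimum.
#'
#' @param x An [attention_problem()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `value`.
#' @export
tidy.attention_problem <- function(x, ...) {
  tibble::tibble(
    term = c("reward_incentive", "info_cost", "prior_precision", "lambda_star"),
    value = c(x$reward_incentive, x$info_cost, x$prior_precision,
              optimal_precision(x))
  )
}

#' @export
glance.attention_problem <- function(x, ...) {
  lam <- optimal_precision(x)
  tibble::tibble(lambda_star = lam,
                 posterior_precision = lam + x$prior_precision,
                 attending = lam > 0,
                 objective_at_optimum = attentional_objective(lam, x))
}

unclass_result <- function(x) {
  attr(x, "experiment") <- NULL
  attr(x, "parameters") <- NULL
  attr(x, "seed") <- NULL
  attr(x, "version") <- NULL
  class(x) <- setdiff(class(x), "experiment_result")
  x
}
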