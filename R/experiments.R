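#' Experiment configuration
#'
#' A named experiment plus parameter overrides and a seed. Defaults for every
#' experiment are the published simulation recipes; any override is recorded
#' in the result metadata. See [list_experiments()] for valid names.
#'
#' @param experiment_name One of the registered experiment names.
#' @param parameters Named list of parameter overrides (may be empty).
#' @param seed Integer seed threaded to any stochastic component.
#' @param output_dir Optional directory; when given, [run_experiment()]
#'   writes `<name>.csv` and `<name>.json` metadata there.
#' @return An object of class `experiment_config`.
#' @examples
#' experiment_config("clock_speed")
#' @export
experiment_config <- function(experiment_name, parameters = list(),
                              seed = 1L, output_dir = NULL) {
  if (!is.character(experiment_name) || length(experiment_name) != 1L ||
      !experiment_name %in% list_experiments()) {
    stop("Unknown experiment. Valid names: ",
         paste(list_experiments(), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.list(parameters))
  if (length(parameters) && is.null(names(parameters))) {
    stop("`parameters` must be a named list.", call. = FALSE)
  }
  structure(list(experiment_name = experiment_name,
                 parameters = parameters,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Registered experiment names
#'
#' @return Character vector of names accepted by [run_experiment()].
#' @export
list_experiments <- function() {
  names(experiment_registry)
}

# Each entry: default parameters + a runner taking the resolved parameter
# list and returning a tibble. Defaults are the published simulation recipes.
experiment_registry <- list(
  lambda_star_curve = list(
    defaults = list(R_max = 2, n_grid = 201, info_cost = 0.5,
                    prior_precision = 0.5),
    run = function(p) {
      precision_incentive_curve(seq(0, p$R_max, length.out = p$n_grid),
                                p$info_cost, p$prior_precision)
    }
  ),
  bandit_winshift = list(
    defaults = list(da_levels = seq(0.55, 0.9, by = 0.05),
                    info_cost = 0.1, prior_precision = 10, beta = 4,
                    magnitude = 1),
    run = function(p) {
      tidyr::expand_grid(da = p$da_levels, risk = c("low", "high")) |>
        purrr::pmap_dfr(function(da, risk) {
          winshift_sim(da, risk, p$info_cost, p$prior_precision, p$beta,
                       p$magnitude)
        })
    }
  ),
  feedback_asymmetry = list(
    defaults = list(da_levels = seq(0.1, 0.9, by = 0.1),
                    info_cost = 0.1, prior_precision = 5),
    run = function(p) {
      purrr::map_dfr(p$da_levels, function(da) {
        acc_pos <- feedback_accuracy(da, 1, p$info_cost, p$prior_precision)
        acc_neg <- feedback_accuracy(da, 0, p$info_cost, p$prior_precision)
        tibble::tibble(da = da, accuracy_pos = acc_pos, accuracy_neg = acc_neg,
                       relative_accuracy = acc_pos - acc_neg)
      })
    }
  ),
  central_tendency = list(
    defaults = list(durations = c(8, 21), da_levels = c(0.2, 1),
                    info_cost = 0.05),
    run = function(p) {
      central_tendency_sim(p$durations, p$da_levels, p$info_cost)
    }
  ),
  clock_speed = list(
    defaults = list(durations = c(7, 17), da_levels = c(0.8, 1, 1.2),
                    info_cost = 0.1, baseline_da = 1),
    run = function(p) {
      clock_speed_sim(p$durations, p$da_levels, p$info_cost, p$baseline_da)
    }
  ),
  controllability = list(
    defaults = list(free_rates = seq(0.005, 0.05, by = 0.005),
                    contingent_rates = c(0.01, 0.02), info_cost = 0.1),
    run = function(p) {
      controllability_clock_sim(p$free_rates, p$contingent_rates, p$info_cost)
    }
  ),
  post_reward_delay = list(
    defaults = list(buffers = c(0, 1, 2, 3, 4, 5, 10), R_pre = 1,
                    R_post = 0.7, info_cost = 0.1),
    run = function(p) {
      post_reward_estimate(p$buffers, p$R_pre, p$R_post, p$info_cost)
    }
  ),
  transfer_choice = list(
    defaults = list(arm_rewards = c(5, 10), precision_high = 1,
                    precision_low = 0.1, prior_precision = 1, beta = 1),
    run = function(p) {
      train_and_transfer(
        training_context(p$arm_rewards, p$precision_high, p$prior_precision),
        training_context(p$arm_rewards, p$precision_low, p$prior_precision),
        p$beta
      )
    }
  ),
  rpe_magnitude = list(
    defaults = list(outcomes = c(5, 10), precision_high = 1,
                    precision_low = 0.1, prior_mean = 7.5,
                    prior_precision = 1),
    run = function(p) {
      prior <- gaussian_belief(p$prior_mean, p$prior_precision)
      tidyr::expand_grid(outcome = p$outcomes,
                         controllability = c("high", "low")) |>
        dplyr::mutate(
          encoding_precision = ifelse(.data$controllability == "high",
                                      p$precision_high, p$precision_low),
          rpe = purrr::map2_dbl(.data$outcome, .data$encoding_precision,
                                ~ rpe_magnitude(.x, .y, prior))
        )
    }
  ),
  gain_vs_inattention = list(
    defaults = list(true_reward = 7.5, prior_mean_c1 = 6.25,
                    prior_mean_c2 = 8.75, encoding_precision = 1,
                    prior_precision = 1, beta_low = 1, beta_high = 10,
                    decode_boost = 10),
    run = function(p) {
      discriminate_gain_vs_ri(p$true_reward, p$prior_mean_c1, p$prior_mean_c2,
                              p$encoding_precision, p$prior_precision,
                              p$beta_low, p$beta_high, p$decode_boost)
    }
  ),
  inverted_u = list(
    defaults = list(R_max = 5, n_grid = 101, info_cost = 0.5,
                    prior_precision = 0.5, lambda_max = 4),
    run = function(p) {
      bounded_performance_curve(seq(0, p$R_max, length.out = p$n_grid),
                                p$info_cost, p$prior_precision, p$lambda_max)
    }
  )
)

#' Run a registered experiment
#'
#' Resolves the configuration's parameters against the experiment's defaults,
#' runs the simulation (deterministic given config and seed), and returns an
#' `experiment_result`: the tidy result tibble carrying the resolved
#' parameters, seed, and experiment name as attributes. If the config names
#' an `output_dir`, a CSV of the table and a JSON metadata file are written
#' there.
#'
#' @param config An [experiment_config()], or an experiment name (then built
#'   with defaults).
#' @param ... When `config` is a name, passed to [experiment_config()].
#' @return An `experiment_result` tibble.
#' @examples
#' res <- run_experiment("clock_speed")
#' glance(res)
#' @export
run_experiment <- function(config, ...) {
  if (is.character(config)) config <- experiment_config(config, ...)
  stopifnot(inherits(config, "experiment_config"))
  entry <- experiment_registry[[config$experiment_name]]
  unknown <- setdiff(names(config$parameters), names(entry$defaults))
  if (length(unknown)) {
    stop("Unknown parameter(s) for ", config$experiment_name, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- utils::modifyList(entry$defaults, config$parameters)
  set.seed(config$seed)
  tab <- entry$run(params)
  res <- tibble::new_tibble(tab,
                            experiment = config$experiment_name,
                            parameters = params,
                            seed = config$seed,
                            version = as.character(utils::packageVersion("rattention")),
                            class = "experiment_result")
  if (!is.null(config$output_dir)) {
    write_experiment_result(res, config$output_dir)
  }
  res
}

#' Write an experiment result as CSV plus JSON metadata
#'
#' The CSV holds the tidy table (comma-separated, header row, '.' decimal,
#' UTF-8); the JSON records the experiment name, resolved parameters, seed,
#' and package version. [read_experiment_result()] restores the result
#' losslessly.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_experiment_result <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- attr(result, "experiment")
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(result), csv, row.names = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(experiment = name,
               parameters = attr(result, "parameters"),
               seed = attr(result, "seed"),
               version = attr(result, "version"))
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("experiment %s: %d rows -> %s", name, nrow(result), csv))
  invisible(csv)
}

#' @rdname write_experiment_result
#' @param path Path to a CSV written by [write_experiment_result()].
#' @export
read_experiment_result <- function(path) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  tibble::new_tibble(tab,
                     experiment = meta$experiment,
                     parameters = meta$parameters,
                     seed = meta$seed,
                     version = meta$version,
                     class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: %s> (seed %s)\n",
              attr(x, "experiment"), attr(x, "seed")))
  NextMethod()
}

#' Synthetic trial streams for property tests
#'
#' Generates seeded stochastic fixtures: Bernoulli outcome sequences for the
#' three-armed bandit under both risk conditions, and noisy encoded-interval
#' samples (subjective-space Gaussian draws at precision `l`). These emulate
#' the trial-by-trial randomness the deterministic figure-level recipes
#' average over.
#'
#' @param seed Integer seed.
#' @param n_trials Trials per bandit arm.
#' @param durations Durations (seconds) for the interval stream.
#' @param n_intervals Encoded samples per duration.
#' @param mapping A [time_mapping()] for the interval stream.
#' @return A list with tibbles `bandit` (columns `risk`, `arm`, `trial`,
#'   `rewarded`) and `intervals` (columns `duration_s`, `m`).
#' @export
generate_fixtures <- function(seed, n_trials = 1000, durations = c(7, 17),
                              n_intervals = 500,
                              mapping = time_mapping(5)) {
  set.seed(seed)
  bandit <- purrr::map_dfr(c("low", "high"), function(risk) {
    arms <- bandit_arms(risk)
    purrr::map_dfr(seq_len(nrow(arms)), function(i) {
      tibble::tibble(risk = risk, arm = arms$arm[i],
                     trial = seq_len(n_trials),
                     rewarded = stats::rbinom(n_trials, 1,
                                              arms$reward_probability[i]))
    })
  })
  intervals <- purrr::map_dfr(durations, function(mu) {
    tibble::tibble(
      duration_s = mu,
      m = stats::rnorm(n_intervals, to_subjective(mu, mapping),
                       1 / sqrt(mapping$subjective_precision))
    )
  })
  list(bandit = bandit, intervals = intervals)
}
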