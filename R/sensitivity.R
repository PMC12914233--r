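#' One-way sensitivity sweep over a simulation parameter
#'
#' Re-runs [run_experiment()] while varying one parameter of the agent-based
#' model, holding everything else (including the base seed) fixed, so runs
#' differ only in the swept parameter. Supported parameters:
#' `initial_trust_mean` (the agents' initial trust distribution is
#' location-shifted to the target mean, then clamped to \[1, 5\]),
#' `broadcast_penalty` (the strategy is forced to `"broadcast"`),
#' `reward_magnitude` (strategy `"reward"`), and `rewire_interval_days`
#' (strategy `"rewire"`).
#'
#' @param records Survey records.
#' @param fit A `delay_fit` with terms trust, frequency, chronic.
#' @param parameter One of `"initial_trust_mean"`, `"broadcast_penalty"`,
#'   `"reward_magnitude"`, `"rewire_interval_days"`.
#' @param values Numeric vector of parameter values (non-empty).
#' @param config Base [abm_config()].
#' @return A list of class `"sensitivity_sweep"`: `long` (tibble with
#'   columns `parameter`, `value`, `day`, `delay_rate`, `mean_trust`),
#'   `summary` (day 1/7/14 delay rates per value, using the last day when
#'   the run is shorter than 14 days), and `runs` (the per-value
#'   `trust_trajectory` objects).
#' @export
sweep_parameter <- function(records, fit,
                            parameter = c("initial_trust_mean",
                                          "broadcast_penalty",
                                          "reward_magnitude",
                                          "rewire_interval_days"),
                            values,
                            config = abm_config()) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) {
    stop("`values` must be non-empty.", call. = FALSE)
  }
  runs <- lapply(values, function(v) {
    cfg <- config
    switch(parameter,
      initial_trust_mean = {
        cfg$init_trust_mean <- v
      },
      broadcast_penalty = {
        cfg$strategy <- "broadcast"
        cfg$broadcast_penalty <- v
      },
      reward_magnitude = {
        cfg$strategy <- "reward"
        cfg$reward_magnitude <- v
      },
      rewire_interval_days = {
        cfg$strategy <- "rewire"
        cfg$rewire_interval_days <- as.integer(v)
      }
    )
    run_experiment(records, fit, cfg)
  })
  names(runs) <- as.character(values)

  long <- purrr::map_dfr(seq_along(values), function(i) {
    tibble::tibble(
      parameter = parameter,
      value = values[i],
      day = runs[[i]]$by_day$day,
      delay_rate = runs[[i]]$by_day$delay_rate,
      mean_trust = runs[[i]]$by_day$mean_trust
    )
  })
  probe_days <- intersect(c(1L, 7L, 14L), unique(long$day))
  if (!max(long$day) %in% probe_days) {
    probe_days <- sort(unique(c(probe_days, max(long$day))))
  }
  summary <- tidyr::pivot_wider(
    dplyr::filter(long, .data$day %in% probe_days),
    id_cols = c("parameter", "value"),
    names_from = "day", values_from = "delay_rate",
    names_prefix = "delay_day"
  )
  structure(list(long = long, summary = summary, runs = runs),
            class = "sensitivity_sweep")
}

#' @export
print.sensitivity_sweep <- function(x, ...) {
  cat("<sensitivity_sweep> parameter =", x$long$parameter[1], "\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.sensitivity_sweep <- function(object, ...) {
  ggplot2::ggplot(
    object$long,
    ggplot2::aes(x = .data$day, y = .data$delay_rate,
                 colour = factor(.data$value))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = "Delay rate",
                  colour = object$long$parameter[1]) +
    ggplot2::theme_minimal()
}
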