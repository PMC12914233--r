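#' The six standard counterfactual scenarios
#'
#' Returns the scenario grid used to translate the fitted three-predictor
#' delay model into group-level predicted probabilities: (1) baseline with
#' moderate trust and usage and no chronic disease; (2) trust raised to 5;
#' (3) usage frequency raised to 5; (4) chronic disease present; (5) trust
#' and frequency both raised; (6) trust, frequency, and chronic disease all
#' set. `NA` means "keep each respondent's observed value".
#'
#' @return A tibble with columns `label`, `trust`, `frequency`, `chronic`
#'   (six rows, in this order).
#' @export
#' @examples
#' default_scenarios()
default_scenarios <- function() {
  tibble::tibble(
    label = c("baseline", "high_trust", "high_frequency", "chronic",
              "high_trust_frequency", "high_trust_frequency_chronic"),
    trust = c(3, 5, 3, 3, 5, 5),
    frequency = c(3, 3, 5, 3, 5, 5),
    chronic = c(0, 0, 0, 1, 0, 1)
  )
}

#' Mean predicted delay probability under counterfactual scenarios
#'
#' For each scenario, the overridden covariates are set to the scenario
#' value for every respondent, all other covariates keep their observed
#' values, and the fitted model's predicted delay probabilities are averaged
#' over respondents. With a model whose covariates are all overridden the
#' average collapses to a single shared probability; the averaging is kept
#' so that richer models work unchanged.
#'
#' @param fit A `delay_fit` (typically `delay ~ trust + frequency +
#'   chronic`).
#' @param records Respondent records supplying the observed covariates.
#' @param specs Scenario tibble as from [default_scenarios()]: a `label`
#'   column plus one column per overridable covariate, `NA` meaning
#'   "observed".
#' @return A tibble with columns `label` and `mean_prob`.
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 800, seed = 4))
#' fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
#' simulate_scenarios(fit, pop, default_scenarios())
simulate_scenarios <- function(fit, records, specs = default_scenarios()) {
  stopifnot(inherits(fit, "delay_fit"))
  override_cols <- setdiff(names(specs), "label")
  model_vars <- fit$predictors
  bad <- override_cols[!override_cols %in% model_vars &
                         vapply(override_cols,
                                function(cl) any(!is.na(specs[[cl]])),
                                logical(1))]
  if (length(bad)) {
    stop("Scenario overrides field(s) absent from the fitted model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    nd <- records
    for (cl in override_cols) {
      v <- specs[[cl]][i]
      if (!is.na(v)) nd[[cl]] <- v
    }
    tibble::tibble(label = specs$label[i],
                   mean_prob = mean(predict(fit, nd)))
  })
}

#' Bar chart of scenario probabilities
#'
#' @param scenarios Output of [simulate_scenarios()].
#' @return A ggplot object.
#' @export
plot_scenarios <- function(scenarios) {
  scenarios$label <- factor(scenarios$label, levels = scenarios$label)
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(x = .data$label, y = .data$mean_prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Mean predicted delay probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
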