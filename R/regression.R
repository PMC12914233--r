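#' Univariate screen of candidate predictors
#'
#' Fits one single-predictor logistic model of the outcome per candidate
#' variable and collects the results in a single table, preserving the input
#' order. Candidates with zero variance are returned as flagged rows (all
#' estimates `NA`) rather than dropped, so the screen always has one row
#' (per term) for every candidate.
#'
#' @param records Respondent records.
#' @param candidates Character vector of candidate predictor columns.
#' @param outcome Binary outcome column (default `"delay"`).
#' @return A tibble with columns `variable`, `term`, `estimate`,
#'   `std.error`, `p.value`, `odds.ratio`, `conf.low`, `conf.high`, and
#'   `note` (`"ok"` or `"zero_variance"`).
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 800, seed = 5))
#' univariate_screen(pop, c("trust", "frequency", "chronic"))
univariate_screen <- function(records, candidates, outcome = "delay") {
  if (length(candidates) == 0L) {
    return(tibble::tibble(
      variable = character(), term = character(), estimate = numeric(),
      std.error = numeric(), p.value = numeric(), odds.ratio = numeric(),
      conf.low = numeric(), conf.high = numeric(), note = character()
    ))
  }
  purrr::map_dfr(candidates, function(v) {
    if (length(unique(stats::na.omit(records[[v]]))) < 2L) {
      return(tibble::tibble(
        variable = v, term = v, estimate = NA_real_, std.error = NA_real_,
        p.value = NA_real_, odds.ratio = NA_real_, conf.low = NA_real_,
        conf.high = NA_real_, note = "zero_variance"
      ))
    }
    fit <- fit_logistic(records, outcome, v)
    tt <- fit$terms[fit$terms$term != "(Intercept)", ]
    tibble::tibble(
      variable = v, term = tt$term, estimate = tt$estimate,
      std.error = tt$std.error, p.value = tt$p.value,
      odds.ratio = tt$odds.ratio, conf.low = tt$conf.low,
      conf.high = tt$conf.high,
      note = if (fit$converged) "ok" else "not_converged"
    )
  })
}

#' Hierarchical (nested) delay models
#'
#' Fits the four nested logistic models used to assess how blocks of
#' covariates contribute to delayed care-seeking: model 1 adjusts for
#' individual characteristics (age, sex, chronic disease); model 2 adds AI
#' recommendation exposure; model 3 adds AI usage patterns (trust and usage
#' frequency); model 4 (fully adjusted) adds willingness to recommend.
#'
#' @param records Respondent records containing `age`, `sex`, `chronic`,
#'   `exposure`, `trust`, `frequency`, `willingness`, and the outcome.
#' @param outcome Binary outcome column (default `"delay"`).
#' @return A named list of four `delay_fit` objects (`model1` .. `model4`),
#'   of class `"hierarchical_fits"`.
#' @export
hierarchical_models <- function(records, outcome = "delay") {
  blocks <- list(
    model1 = c("age", "sex", "chronic"),
    model2 = c("age", "sex", "chronic", "exposure"),
    model3 = c("age", "sex", "chronic", "exposure", "trust", "frequency"),
    model4 = c("age", "sex", "chronic", "exposure", "trust", "frequency",
               "willingness")
  )
  needed <- unique(unlist(blocks))
  missing_cols <- setdiff(c(needed, outcome), names(records))
  if (length(missing_cols)) {
    stop("`records` lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fits <- lapply(blocks, function(p) fit_logistic(records, outcome, p))
  structure(fits, class = "hierarchical_fits")
}

#' @export
tidy.hierarchical_fits <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) {
    dplyr::mutate(tidy(x[[nm]]), model = nm, .before = 1)
  })
}

#' @export
print.hierarchical_fits <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Stratified logistic analysis
#'
#' Fits the same logistic model within each stratum of a partition of the
#' records, e.g. the pre/post split at a large-language-model release date,
#' or low versus high recommendation exposure.
#'
#' @param records Respondent records.
#' @param by Either the name of an existing grouping column or a function
#'   mapping the records tibble to a vector of stratum labels.
#' @param outcome Binary outcome column.
#' @param predictors Predictors of the per-stratum model.
#' @return A tibble of per-stratum tidied fits with columns `stratum`, `n`,
#'   plus the [tidy.delay_fit()] columns; strata too degenerate to fit are
#'   flagged in `note`. The fit objects are attached as attribute `"fits"`.
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 1500, seed = 9))
#' stratified_analysis(pop, stratify_period(), "delay",
#'                     c("trust", "frequency", "chronic"))
stratified_analysis <- function(records, by, outcome = "delay",
                                predictors = c("trust", "frequency",
                                               "chronic")) {
  labels <- if (is.function(by)) by(records) else records[[by]]
  labels <- as.character(labels)
  strata <- unique(labels)
  if (length(strata) < 2L) {
    stop("Stratifier produced fewer than 2 non-empty strata.", call. = FALSE)
  }
  fits <- list()
  rows <- purrr::map_dfr(strata, function(s) {
    sub <- records[labels == s, , drop = FALSE]
    res <- tryCatch(fit_logistic(sub, outcome, predictors),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      return(tibble::tibble(stratum = s, n = nrow(sub), term = NA_character_,
                            estimate = NA_real_, std.error = NA_real_,
                            statistic = NA_real_, p.value = NA_real_,
                            odds.ratio = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, note = res))
    }
    fits[[s]] <<- res
    dplyr::mutate(tidy(res), stratum = s, n = res$n_obs, .before = 1,
                  note = if (res$converged) "ok" else "not_converged")
  })
  attr(rows, "fits") <- fits
  rows
}

#' Stratifier helpers
#'
#' `stratify_period()` splits records at a cutoff submission date (default
#' 2025-02-01, the public-release shock used for the robustness check);
#' `stratify_exposure()` splits at recommendation-exposure score <= 2 versus
#' > 2; `stratify_willingness()` splits at willingness <= 2 versus >= 3.
#' Each returns a function suitable for the `by` argument of
#' [stratified_analysis()].
#'
#' @param cutoff Cutoff date for `stratify_period()`.
#' @return A function mapping a records tibble to stratum labels.
#' @export
stratify_period <- function(cutoff = as.Date("2025-02-01")) {
  function(records) {
    ifelse(records$submission_date < cutoff, "pre", "post")
  }
}

#' @rdname stratify_period
#' @export
stratify_exposure <- function() {
  function(records) ifelse(records$exposure <= 2, "low", "high")
}

#' @rdname stratify_period
#' @export
stratify_willingness <- function() {
  function(records) ifelse(records$willingness <= 2, "low", "high")
}

#' Moderation analysis with an interaction term
#'
#' Fits a logistic model containing a focal predictor, a binary moderator,
#' their product term, and adjustment covariates, and tabulates predicted
#' delay probabilities over a grid of focal values for each moderator level
#' (adjusters held at their sample means).
#'
#' @param records Respondent records.
#' @param focal Name of the focal continuous predictor (e.g. `"trust"`).
#' @param moderator Name of the moderator column, or a function mapping the
#'   records to a binary 0/1 vector (e.g. a grouping rule).
#' @param adjusters Adjustment covariate names.
#' @param outcome Binary outcome column.
#' @return A list of class `"interaction_fit"`: `fit` (the full `delay_fit`),
#'   `interaction` (one-row tibble for the product term), and `pred_grid`
#'   (tibble of predicted probabilities by focal value and moderator level).
#' @export
interaction_model <- function(records, focal, moderator,
                              adjusters = c("age", "sex", "chronic",
                                            "frequency"),
                              outcome = "delay") {
  mod_vals <- if (is.function(moderator)) moderator(records)
              else records[[moderator]]
  mod_vals <- as.numeric(mod_vals)
  if (length(unique(stats::na.omit(mod_vals))) < 2L) {
    stop("Moderator is constant; no interaction can be estimated.",
         call. = FALSE)
  }
  if (!all(stats::na.omit(mod_vals) %in% c(0, 1))) {
    stop("Moderator must be binary (0/1) after grouping.", call. = FALSE)
  }
  df <- dplyr::mutate(records, .moderator = mod_vals,
                      .interaction = .data[[focal]] * mod_vals)
  fit <- fit_logistic(df, outcome,
                      c(focal, ".moderator", ".interaction", adjusters))
  int_row <- fit$terms[fit$terms$term == ".interaction", ]

  focal_grid <- seq(min(df[[focal]], na.rm = TRUE),
                    max(df[[focal]], na.rm = TRUE))
  base <- lapply(adjusters, function(a) {
    v <- df[[a]]
    if (is.numeric(v)) mean(v, na.rm = TRUE) else {
      factor(levels(v)[1], levels = levels(v))
    }
  })
  names(base) <- adjusters
  grid <- tidyr::expand_grid(focal = focal_grid, .moderator = c(0, 1))
  newdata <- tibble::as_tibble(c(
    stats::setNames(list(grid$focal), focal),
    list(.moderator = grid$.moderator,
         .interaction = grid$focal * grid$.moderator),
    lapply(base, function(v) rep(v, nrow(grid)))
  ))
  grid$pred_prob <- predict(fit, newdata)
  names(grid)[1] <- focal

  structure(
    list(fit = fit, interaction = int_row, pred_grid = grid),
    class = "interaction_fit"
  )
}

#' @export
tidy.interaction_fit <- function(x, ...) tidy(x$fit)

#' @export
print.interaction_fit <- function(x, ...) {
  cat("<interaction_fit>\n")
  cat("Interaction term:\n")
  print(x$interaction)
  invisible(x)
}

#' @export
autoplot.interaction_fit <- function(object, ...) {
  focal <- names(object$pred_grid)[1]
  ggplot2::ggplot(
    object$pred_grid,
    ggplot2::aes(x = .data[[focal]], y = .data$pred_prob,
                 colour = factor(.data$.moderator))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = focal, y = "Predicted delay probability",
                  colour = "Moderator") +
    ggplot2::theme_minimal()
}
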