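#' Fit a logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic regression (binomial GLM, iteratively
#' reweighted least squares) of a binary outcome on a set of predictors,
#' reported on the odds-ratio scale with Wald 95% confidence intervals
#' (`exp(beta +/- 1.96 SE)`) and two-sided Wald p-values. Factors are
#' expanded with treatment contrasts: `sex` with female as reference,
#' `occupation` with students as reference.
#'
#' Fits that fail to converge within `max_iter` IRLS iterations, or that show
#' the diverging coefficients characteristic of complete separation
#' (`|beta| > 15`), are returned with `converged = FALSE` / `separation =
#' TRUE` rather than silently clipped. A constant outcome is an error.
#'
#' @param records Data frame of respondent records.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of predictor column names.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#'
#' @return An object of class `"delay_fit"`; see [tidy.delay_fit()] and
#'   [glance.delay_fit()].
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 800, seed = 11))
#' fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
#' tidy(fit)
fit_logistic <- function(records, outcome, predictors,
                         max_iter = 100L, tol = 1e-8) {
  stopifnot(is.data.frame(records))
  if (!outcome %in% names(records)) {
    stop("Outcome `", outcome, "` not found in `records`.", call. = FALSE)
  }
  missing_pred <- setdiff(predictors, names(records))
  if (length(missing_pred)) {
    stop("Missing predictor column(s): ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  }
  y <- records[[outcome]]
  if (length(unique(stats::na.omit(y))) < 2L) {
    stop("Outcome `", outcome, "` is constant; cannot fit.", call. = FALSE)
  }

  zero_var <- predictors[vapply(
    predictors,
    function(p) length(unique(stats::na.omit(records[[p]]))) < 2L,
    logical(1)
  )]

  fml <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(stats::glm(
    fml, data = records, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))

  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(abs(beta[is.finite(beta)]) > 15)
  converged <- isTRUE(fit$converged) && !separation && !anyNA(beta)

  terms_tbl <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se)[match(names(beta), names(se))],
    statistic = unname(beta) / unname(se)[match(names(beta), names(se))],
    p.value = 2 * stats::pnorm(-abs(unname(beta) /
                                      unname(se)[match(names(beta), names(se))])),
    odds.ratio = exp(unname(beta)),
    conf.low = exp(unname(beta) - 1.96 * unname(se)[match(names(beta), names(se))]),
    conf.high = exp(unname(beta) + 1.96 * unname(se)[match(names(beta), names(se))])
  )

  structure(
    list(
      outcome = outcome,
      predictors = predictors,
      terms = terms_tbl,
      model = fit,
      n_obs = stats::nobs(fit),
      converged = converged,
      separation = separation,
      zero_variance = zero_var,
      encoding = c(sex = "female = reference",
                   occupation = "students = reference")
    ),
    class = "delay_fit"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted delay model
#'
#' @param x A `delay_fit` from [fit_logistic()].
#' @param ... Unused.
#' @return A tibble with one row per model term: log-odds `estimate`,
#'   `std.error`, Wald `statistic` and `p.value`, and `odds.ratio` with
#'   Wald 95% `conf.low`/`conf.high` on the OR scale.
#' @export
tidy.delay_fit <- function(x, ...) x$terms

#' @rdname tidy.delay_fit
#' @return `glance()`: a one-row tibble with `n_obs`, `logLik`, `AIC`,
#'   `deviance`, `converged`, and `separation`.
#' @export
glance.delay_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    logLik = as.numeric(stats::logLik(x$model)),
    AIC = stats::AIC(x$model),
    deviance = stats::deviance(x$model),
    converged = x$converged,
    separation = x$separation
  )
}

#' @export
print.delay_fit <- function(x, ...) {
  cat("<delay_fit> ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  cat("  n = ", x$n_obs,
      if (!x$converged) "  [NOT CONVERGED]" else "",
      if (x$separation) "  [SEPARATION SUSPECTED]" else "", "\n", sep = "")
  print(x$terms, n = Inf)
  invisible(x)
}

#' Predicted delay probabilities from a fitted model
#'
#' @param object A `delay_fit`.
#' @param newdata Data frame of covariates (defaults to the training data).
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.delay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    as.numeric(stats::fitted(object$model))
  } else {
    as.numeric(stats::predict(object$model, newdata = newdata,
                              type = "response"))
  }
}

#' Forest plot of odds ratios
#'
#' @param object A `delay_fit`.
#' @param ... Unused.
#' @return A ggplot object showing each non-intercept term's odds ratio and
#'   Wald 95% CI on a log scale.
#' @export
autoplot.delay_fit <- function(object, ...) {
  d <- object$terms[object$terms$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds.ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
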