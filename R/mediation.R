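#' Baron-Kenny path estimation for trust -> frequency -> delay
#'
#' Estimates the mediation paths of the effect of AI trust on delayed
#' care-seeking through AI usage frequency: path `a` (frequency on trust,
#' ordinary least squares), paths `b` and `c'` (delay on trust and frequency,
#' logistic regression, so on the log-odds scale), and the total effect `c`
#' (delay on trust with the mediator omitted). All four models are adjusted
#' for the supplied covariates. The indirect effect is the product `a * b`,
#' with significance assessed by the Sobel z test. Because the outcome
#' models are logistic, `c` and `c' + a*b` need not agree exactly
#' (non-collapsibility of the odds ratio); the decomposition is on the
#' log-odds scale, as is conventional for this design.
#'
#' @param records Respondent records.
#' @param adjusters Adjustment covariates (default age, sex, chronic).
#' @param exposure,mediator,outcome Column names of the exposure, mediator,
#'   and binary outcome.
#' @return An object of class `"mediation_result"` with components `a`,
#'   `se_a`, `b`, `se_b`, `c`, `c_prime`, `se_c_prime`, `indirect`
#'   (`= a * b`), `sobel_z`, `sobel_p`, and (after
#'   [bootstrap_indirect()]) `boot_mean`, `boot_ci`, `boot_p`, `n_boot`,
#'   `boot_reps`.
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 1000, seed = 2))
#' estimate_paths(pop)
estimate_paths <- function(records,
                           adjusters = c("age", "sex", "chronic"),
                           exposure = "trust", mediator = "frequency",
                           outcome = "delay") {
  for (col in c(exposure, mediator, outcome, adjusters)) {
    if (!col %in% names(records)) {
      stop("`records` lacks column `", col, "`.", call. = FALSE)
    }
  }
  # path a: mediator ~ exposure + adjusters (linear)
  fml_a <- stats::reformulate(c(exposure, adjusters), response = mediator)
  fit_a <- stats::lm(fml_a, data = records)
  a <- stats::coef(fit_a)[[exposure]]
  se_a <- sqrt(diag(stats::vcov(fit_a)))[[exposure]]

  # paths b and c': outcome ~ exposure + mediator + adjusters (logistic)
  fit_bc <- fit_logistic(records, outcome, c(exposure, mediator, adjusters))
  b <- fit_bc$terms$estimate[fit_bc$terms$term == mediator]
  se_b <- fit_bc$terms$std.error[fit_bc$terms$term == mediator]
  c_prime <- fit_bc$terms$estimate[fit_bc$terms$term == exposure]
  se_c_prime <- fit_bc$terms$std.error[fit_bc$terms$term == exposure]

  # total effect c: outcome ~ exposure + adjusters (mediator omitted)
  fit_c <- fit_logistic(records, outcome, c(exposure, adjusters))
  c_total <- fit_c$terms$estimate[fit_c$terms$term == exposure]

  sob <- sobel_test(a, se_a, b, se_b)

  structure(
    list(
      a = a, se_a = se_a, b = b, se_b = se_b,
      c = c_total, c_prime = c_prime, se_c_prime = se_c_prime,
      indirect = a * b,
      sobel_z = sob$z, sobel_p = sob$p,
      boot_mean = NA_real_, boot_ci = c(NA_real_, NA_real_),
      boot_p = NA_real_, n_boot = 0L, boot_reps = numeric(),
      boot_flagged = FALSE,
      adjusters = adjusters, exposure = exposure, mediator = mediator,
      outcome = outcome
    ),
    class = "mediation_result"
  )
}

#' Sobel z test for a product of coefficients
#'
#' Normal-approximation test of an indirect effect `a * b`:
#' `z = a * b / sqrt(b^2 se_a^2 + a^2 se_b^2)`, with a two-sided normal
#' p-value. The sign of `z` equals the sign of `a * b`.
#'
#' @param a,b Path estimates.
#' @param se_a,se_b Their standard errors (must be positive).
#' @return A list with elements `z` and `p`.
#' @export
#' @examples
#' sobel_test(0.5754, 0.014, 0.3387, 0.0455)
sobel_test <- function(a, se_a, b, se_b) {
  if (!is.numeric(se_a) || !is.numeric(se_b) || se_a <= 0 || se_b <= 0) {
    stop("Standard errors must be positive.", call. = FALSE)
  }
  denom <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- if (denom == 0) 0 else a * b / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Nonparametric bootstrap of the indirect effect
#'
#' Resamples the records with replacement at full sample size, re-estimates
#' paths `a` and `b` in each replicate, and summarises the empirical
#' distribution of `a * b`: bootstrap mean, 2.5/97.5 percentile confidence
#' bounds (order statistics, no normal approximation), and a bootstrap
#' p-value defined as twice the smaller tail proportion of replicates at or
#' beyond zero. Replicates whose outcome model fails to converge are dropped
#' and counted; if more than 20% fail, the result is flagged.
#'
#' @param records Respondent records.
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Integer seed for the resampling.
#' @param adjusters,exposure,mediator,outcome As in [estimate_paths()].
#' @return A completed `"mediation_result"` (point estimates from the full
#'   sample, bootstrap fields filled in).
#' @export
bootstrap_indirect <- function(records, n_boot = 500L, seed = 1L,
                               adjusters = c("age", "sex", "chronic"),
                               exposure = "trust", mediator = "frequency",
                               outcome = "delay") {
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop("`n_boot` must be at least 1.", call. = FALSE)
  }
  res <- estimate_paths(records, adjusters, exposure, mediator, outcome)
  n <- nrow(records)
  set.seed(as.integer(seed))

  fml_a <- stats::reformulate(c(exposure, adjusters), response = mediator)
  fml_b <- stats::reformulate(c(exposure, mediator, adjusters),
                              response = outcome)
  reps <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- records[idx, , drop = FALSE]
    est <- tryCatch({
      a_i <- stats::coef(stats::lm(fml_a, data = boot))[[exposure]]
      gl <- suppressWarnings(stats::glm(fml_b, data = boot,
                                        family = stats::binomial()))
      b_i <- stats::coef(gl)[[mediator]]
      if (!isTRUE(gl$converged) || abs(b_i) > 15) NA_real_ else a_i * b_i
    }, error = function(e) NA_real_)
    reps[i] <- est
  }
  ok <- reps[!is.na(reps)]
  res$boot_reps <- ok
  res$n_boot <- length(ok)
  res$boot_flagged <- (n_boot - length(ok)) / n_boot > 0.20
  if (length(ok)) {
    res$boot_mean <- mean(ok)
    res$boot_ci <- unname(stats::quantile(ok, c(0.025, 0.975), type = 1))
    res$boot_p <- min(1, 2 * min(mean(ok <= 0), mean(ok >= 0)))
  }
  res
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    path = c("a", "b", "indirect", "c", "c_prime"),
    estimate = c(x$a, x$b, x$indirect, x$c, x$c_prime),
    std.error = c(x$se_a, x$se_b, NA, NA, x$se_c_prime),
    odds.ratio = c(NA, exp(x$b), exp(x$indirect), exp(x$c), exp(x$c_prime))
  )
}

#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    indirect = x$indirect, sobel_z = x$sobel_z, sobel_p = x$sobel_p,
    boot_mean = x$boot_mean, boot_low = x$boot_ci[1],
    boot_high = x$boot_ci[2], boot_p = x$boot_p, n_boot = x$n_boot,
    boot_flagged = x$boot_flagged
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> ", x$exposure, " -> ", x$mediator, " -> ",
      x$outcome, "\n", sep = "")
  cat(sprintf("  a        = %.4f (SE %.4f)\n", x$a, x$se_a))
  cat(sprintf("  b        = %.4f (SE %.4f)  [log-odds]\n", x$b, x$se_b))
  cat(sprintf("  indirect = %.4f (OR %.3f)\n", x$indirect, exp(x$indirect)))
  cat(sprintf("  c        = %.4f   c' = %.4f\n", x$c, x$c_prime))
  cat(sprintf("  Sobel z = %.3f, p = %.3g\n", x$sobel_z, x$sobel_p))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap (n=%d): mean %.4f, 95%% CI [%.4f, %.4f], p %s\n",
                x$n_boot, x$boot_mean, x$boot_ci[1], x$boot_ci[2],
                format.pval(x$boot_p)))
    if (x$boot_flagged) cat("  [>20% of replicates failed]\n")
  }
  invisible(x)
}

#' Histogram of the bootstrap indirect-effect distribution
#'
#' @param object A `mediation_result` with bootstrap replicates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_result <- function(object, ...) {
  if (!length(object$boot_reps)) {
    stop("No bootstrap replicates; run bootstrap_indirect() first.",
         call. = FALSE)
  }
  df <- tibble::tibble(indirect = object$boot_reps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indirect)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = object$indirect, linetype = "dashed") +
    ggplot2::labs(x = "Bootstrap indirect effect (a x b)", y = "Replicates") +
    ggplot2::theme_minimal()
}
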