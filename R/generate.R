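#' Calibrate the delay-model intercept to a target prevalence
#'
#' Finds, by bisection, the intercept `b0` such that the mean of
#' `plogis(b0 + X beta)` over a sample of covariates equals a target marginal
#' outcome rate. The mean logistic response is strictly increasing in the
#' intercept, so the root is unique.
#'
#' @param coefs Named numeric vector of generating log-odds-ratios; names
#'   must be columns of `covariates`.
#' @param covariates Data frame holding one column per name in `coefs`.
#' @param target_rate Target marginal rate, strictly between 0 and 1.
#' @param tol Convergence tolerance on the achieved mean rate.
#' @param max_iter Maximum bisection iterations.
#'
#' @return The calibrated intercept (scalar, log-odds scale).
#' @export
#' @examples
#' df <- data.frame(trust = rep(0:5, 10))
#' calibrate_intercept(c(trust = 0), df, 0.5) # exactly 0
calibrate_intercept <- function(coefs, covariates, target_rate,
                                tol = 1e-6, max_iter = 200L) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0 || target_rate >= 1) {
    stop("`target_rate` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (nrow(covariates) == 0L) {
    stop("`covariates` must contain at least one row.", call. = FALSE)
  }
  missing_cols <- setdiff(names(coefs), names(covariates))
  if (length(missing_cols)) {
    stop("`covariates` lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  eta <- rep(0, nrow(covariates))
  for (nm in names(coefs)) {
    eta <- eta + coefs[[nm]] * as.numeric(covariates[[nm]])
  }
  mean_rate <- function(b0) mean(stats::plogis(b0 + eta))

  lo <- -50; hi <- 50
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- mean_rate(mid)
    if (abs(r - target_rate) < tol) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  stop("Intercept calibration did not converge after ", max_iter,
       " iterations.", call. = FALSE)
}

#' Generate a synthetic survey population
#'
#' Draws `n_respondents` respondent records with the generating structure of
#' the emulated survey: trust sampled from its six-level marginal
#' distribution; usage frequency linked to trust by a linear-Gaussian model
#' (`round(clamp(slope * trust + noise, 0, 5))`, with frequency forced to 0
#' whenever trust is 0, since a respondent who never used AI advice cannot
#' report a usage frequency); chronic disease Bernoulli and independent of
#' trust; and a binary delay outcome drawn from a logistic model in trust,
#' frequency, and chronic status whose intercept is calibrated so the mean
#' predicted delay probability matches the configured target prevalence.
#' Age, sex, occupation, exposure, willingness, and submission dates carry
#' the configured marginals but have no generating effect on delay.
#'
#' When `dirty_fraction > 0`, that fraction of records is corrupted to
#' violate one of the data-cleaning rules (completion under 90 seconds,
#' duplicated id, missing value, or trust 0 with positive frequency) so that
#' [apply_exclusions()] can be exercised on a raw-stream-like sample.
#'
#' @param config A [survey_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A tibble with one row per respondent and columns `id`, `age`,
#'   `sex`, `occupation`, `trust`, `frequency`, `chronic`, `delay`,
#'   `exposure`, `willingness`, `submission_date`, `completion_seconds`.
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 200, seed = 7))
#' table(pop$trust)
generate_population <- function(config = survey_config(), seed = config$seed) {
  validate_survey_config(config)
  n <- config$n_respondents
  if (n == 0L) return(empty_survey())

  withr_seed(seed)

  trust <- sample(0:5, n, replace = TRUE, prob = config$trust_probs)
  noise <- stats::rnorm(n, 0, config$path_a_noise_sd)
  frequency <- ifelse(
    trust == 0L, 0,
    round(pmin(5, pmax(0, config$path_a_slope * trust + noise)))
  )
  chronic <- stats::rbinom(n, 1L, config$chronic_prev)

  coefs <- c(trust = config$beta_trust,
             frequency = config$beta_freq,
             chronic = config$beta_chronic)
  covs <- data.frame(trust = trust, frequency = frequency, chronic = chronic)
  b0 <- config$intercept %||%
    calibrate_intercept(coefs, covs, config$target_delay_rate)
  p_delay <- stats::plogis(
    b0 + coefs[["trust"]] * trust + coefs[["frequency"]] * frequency +
      coefs[["chronic"]] * chronic
  )
  delay <- as.integer(stats::runif(n) < p_delay)

  age <- rtrunc_norm(n, recentre_trunc_mean(config$age_mean, config$age_sd,
                                            18, 75),
                     config$age_sd, 18, 75)
  sex <- factor(
    ifelse(stats::runif(n) < config$female_prop, "female", "male"),
    levels = c("female", "male")
  )
  occupation <- factor(
    sample(names(config$occupation_probs), n, replace = TRUE,
           prob = config$occupation_probs),
    levels = names(config$occupation_probs)
  )
  exposure <- sample(1:5, n, replace = TRUE, prob = config$exposure_probs)
  willingness <- sample(1:5, n, replace = TRUE, prob = config$willingness_probs)
  span <- as.integer(config$date_range[2] - config$date_range[1])
  submission_date <- config$date_range[1] + sample(0:span, n, replace = TRUE)
  completion_seconds <- round(90 + stats::rlnorm(n, log(150), 0.5))

  out <- tibble::tibble(
    id = seq_len(n),
    age = age,
    sex = sex,
    occupation = occupation,
    trust = as.integer(trust),
    frequency = as.integer(frequency),
    chronic = as.integer(chronic),
    delay = delay,
    exposure = as.integer(exposure),
    willingness = as.integer(willingness),
    submission_date = submission_date,
    completion_seconds = completion_seconds
  )

  if (config$dirty_fraction > 0 && n > 1L) {
    out <- corrupt_records(out, config$dirty_fraction)
  }
  out
}

# Inject cleaning-rule violations into a clean sample. Each selected record
# gets exactly one violation type, cycling over the four rules.
corrupt_records <- function(records, dirty_fraction) {
  n <- nrow(records)
  n_dirty <- round(dirty_fraction * n)
  if (n_dirty == 0L) return(records)
  idx <- sample(seq_len(n), n_dirty)
  type <- rep_len(c("fast", "duplicate", "missing", "inconsistent"), n_dirty)
  for (k in seq_len(n_dirty)) {
    i <- idx[k]
    switch(type[k],
      fast = {
        records$completion_seconds[i] <- round(stats::runif(1, 20, 85))
      },
      duplicate = {
        pool <- setdiff(seq_len(i - 1L), idx)
        if (length(pool)) {
          donor <- pool[sample.int(length(pool), 1L)]
          records$id[i] <- records$id[donor]
        } else {
          records$completion_seconds[i] <- 60
        }
      },
      missing = {
        col <- sample(c("age", "trust", "frequency", "delay"), 1L)
        records[[col]][i] <- NA
      },
      inconsistent = {
        records$trust[i] <- 0L
        records$frequency[i] <- sample(1:5, 1L)
      }
    )
  }
  records
}

#' Apply the survey data-cleaning filters
#'
#' Enforces the four cleaning rules used on the emulated survey: records
#' completed in under 90 seconds, duplicate ids (the first occurrence is
#' retained), records with missing values in analysis fields, and the
#' logical inconsistency of reporting a positive usage frequency while never
#' having used AI advice (trust 0) are excluded. Each excluded record is
#' counted under the first rule it violates, in the order duplicate, missing,
#' fast completion, inconsistency.
#'
#' @param records A survey tibble as produced by [generate_population()].
#'
#' @return A list with elements `clean` (the retained records) and `report`
#'   (a tibble of exclusion counts by reason, including zero-count reasons).
#' @export
#' @examples
#' raw <- generate_population(survey_config(n_respondents = 300, seed = 3,
#'                                          dirty_fraction = 0.117))
#' res <- apply_exclusions(raw)
#' res$report
apply_exclusions <- function(records) {
  reasons <- c("duplicate", "missing", "fast_completion", "inconsistent")
  if (nrow(records) == 0L) {
    return(list(
      clean = records,
      report = tibble::tibble(reason = reasons, n_excluded = 0L)
    ))
  }
  key_fields <- intersect(
    c("age", "sex", "trust", "frequency", "chronic", "delay",
      "completion_seconds"),
    names(records)
  )
  dup <- duplicated(records$id)
  miss <- !dup & Reduce(`|`, lapply(records[key_fields], is.na))
  fast <- !dup & !miss & !is.na(records$completion_seconds) &
    records$completion_seconds < 90
  incons <- !dup & !miss & !fast &
    !is.na(records$trust) & !is.na(records$frequency) &
    records$trust == 0 & records$frequency > 0
  keep <- !(dup | miss | fast | incons)
  list(
    clean = records[keep, , drop = FALSE],
    report = tibble::tibble(
      reason = reasons,
      n_excluded = c(sum(dup), sum(miss), sum(fast), sum(incons))
    )
  )
}

#' Read or write a survey sample as CSV
#'
#' The CSV schema is the column layout of [generate_population()]; dates are
#' ISO-8601 and `sex`/`occupation` are stored as their level labels.
#'
#' @param records Survey tibble.
#' @param path File path.
#' @return `write_survey()` returns `path` invisibly; `read_survey()` a
#'   survey tibble.
#' @export
write_survey <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sex <- factor(df$sex, levels = c("female", "male"))
  if ("occupation" %in% names(df)) {
    df$occupation <- factor(df$occupation,
                            levels = unique(c("students", "technology",
                                              "other", "healthcare",
                                              df$occupation)))
  }
  if ("submission_date" %in% names(df)) {
    df$submission_date <- as.Date(df$submission_date)
  }
  tibble::as_tibble(df)
}

empty_survey <- function() {
  tibble::tibble(
    id = integer(), age = numeric(),
    sex = factor(character(), levels = c("female", "male")),
    occupation = factor(character(),
                        levels = c("students", "technology", "other",
                                   "healthcare")),
    trust = integer(), frequency = integer(), chronic = integer(),
    delay = integer(), exposure = integer(), willingness = integer(),
    submission_date = as.Date(character()), completion_seconds = numeric()
  )
}

# Location parameter mu such that the [lo, hi]-truncated Normal(mu, sd) has
# the requested mean, so truncation does not shift the realized average.
recentre_trunc_mean <- function(target, sd, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = lo - 3 * sd, upper = hi)$root
}

# Normal truncated to [lo, hi] by inverse-CDF sampling.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
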