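#' Configuration for the synthetic survey generator
#'
#' Builds the parameter set that [generate_population()] uses to draw
#' survey-like respondent records. The defaults reproduce the marginal
#' structure of the study population the package emulates: a six-level trust
#' score (0 = never used AI advice, 1-5 increasing trust) with 38% at level 0,
#' chronic-disease prevalence of 30.1%, 54.7% female, mean age 34.46 (SD
#' 11.62) years, and a binary care-delay outcome generated from a logistic
#' model with odds ratios 1.09 (per trust unit), 1.40 (per frequency unit)
#' and 1.42 (chronic disease), calibrated so the marginal delay prevalence is
#' 11.6%. Usage frequency is linked to trust through a linear-Gaussian model
#' with slope 0.5754 (frequency units per trust unit), rounded and clamped to
#' the 0-5 scale, with the hard constraint that respondents who never used AI
#' (trust 0) have frequency 0.
#'
#' @param n_respondents Number of respondents to generate.
#' @param seed Integer seed controlling all randomness of a generation run.
#' @param trust_probs Probabilities of trust levels 0-5; must sum to 1.
#' @param beta_trust,beta_freq,beta_chronic Generating log-odds-ratios of the
#'   delay outcome per unit trust, per unit frequency, and for chronic
#'   disease.
#' @param intercept Intercept of the delay model on the log-odds scale, or
#'   `NULL` (default) to calibrate it at generation time so that the mean
#'   predicted delay probability over the drawn covariates equals
#'   `target_delay_rate` (see [calibrate_intercept()]).
#' @param path_a_slope Linear slope of usage frequency on trust.
#' @param path_a_noise_sd Standard deviation of the Gaussian noise on the
#'   trust-frequency link (before rounding/clamping). The default 2.0 was
#'   calibrated once so that the refitted path-a and frequency log-odds
#'   standard errors at n = 2460 match the emulated survey's reported
#'   precision (0.014 and 0.0455); after rounding and clamping the effective
#'   residual SD is about 1.4.
#' @param chronic_prev Chronic-disease prevalence.
#' @param target_delay_rate Marginal delay prevalence the intercept is
#'   calibrated to.
#' @param female_prop Proportion female.
#' @param age_mean,age_sd Mean and SD of age in years; ages are truncated to
#'   18-75.
#' @param occupation_probs Probabilities of the four occupation categories
#'   (students, technology workers, other, health care personnel).
#' @param exposure_probs Probabilities over the 1-5 scale of how often the
#'   respondent receives AI recommendations.
#' @param willingness_probs Probabilities over the 1-5 scale of willingness
#'   to recommend AI tools.
#' @param date_range Length-2 `Date` vector; submission dates are uniform
#'   over this window.
#' @param dirty_fraction Fraction of records deliberately corrupted so that
#'   they violate one of the data-cleaning rules enforced by
#'   [apply_exclusions()] (fast completion, duplicate id, missing value, or
#'   the trust-0-with-positive-frequency inconsistency). The default 0
#'   yields an analysis-ready sample; 0.117 emulates the raw submission
#'   stream of the emulated survey (325 of 2785 submissions excluded).
#'
#' @return A list of class `"survey_config"`.
#' @seealso [generate_population()], [apply_exclusions()]
#' @export
#' @examples
#' cfg <- survey_config(n_respondents = 500, seed = 42)
#' pop <- generate_population(cfg)
#' mean(pop$delay)
survey_config <- function(n_respondents = 2460,
                          seed = 1L,
                          trust_probs = c(0.380, 0.130, 0.118, 0.114, 0.140, 0.118),
                          beta_trust = log(1.09),
                          beta_freq = log(1.40),
                          beta_chronic = log(1.42),
                          intercept = NULL,
                          path_a_slope = 0.5754,
                          path_a_noise_sd = 2.0,
                          chronic_prev = 0.301,
                          target_delay_rate = 0.116,
                          female_prop = 0.547,
                          age_mean = 34.46,
                          age_sd = 11.62,
                          occupation_probs = c(students = 0.335,
                                               technology = 0.291,
                                               other = 0.260,
                                               healthcare = 0.114),
                          exposure_probs = c(0.20, 0.25, 0.25, 0.20, 0.10),
                          willingness_probs = c(0.10, 0.20, 0.30, 0.25, 0.15),
                          date_range = as.Date(c("2024-12-01", "2025-05-20")),
                          dirty_fraction = 0) {
  cfg <- list(
    n_respondents = as.integer(n_respondents),
    seed = as.integer(seed),
    trust_probs = trust_probs,
    beta_trust = beta_trust,
    beta_freq = beta_freq,
    beta_chronic = beta_chronic,
    intercept = intercept,
    path_a_slope = path_a_slope,
    path_a_noise_sd = path_a_noise_sd,
    chronic_prev = chronic_prev,
    target_delay_rate = target_delay_rate,
    female_prop = female_prop,
    age_mean = age_mean,
    age_sd = age_sd,
    occupation_probs = occupation_probs,
    exposure_probs = exposure_probs,
    willingness_probs = willingness_probs,
    date_range = as.Date(date_range),
    dirty_fraction = dirty_fraction
  )
  class(cfg) <- "survey_config"
  validate_survey_config(cfg)
  cfg
}

validate_survey_config <- function(cfg) {
  stopifnot(inherits(cfg, "survey_config"))
  if (cfg$n_respondents < 0) {
    stop("`n_respondents` must be non-negative.", call. = FALSE)
  }
  check_prob_vector(cfg$trust_probs, 6L, "trust_probs")
  check_prob_vector(cfg$occupation_probs, 4L, "occupation_probs")
  check_prob_vector(cfg$exposure_probs, 5L, "exposure_probs")
  check_prob_vector(cfg$willingness_probs, 5L, "willingness_probs")
  for (nm in c("chronic_prev", "target_delay_rate", "female_prop",
               "dirty_fraction")) {
    p <- cfg[[nm]]
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("`", nm, "` must be a probability in [0, 1].", call. = FALSE)
    }
  }
  if (cfg$path_a_noise_sd <= 0) {
    stop("`path_a_noise_sd` must be positive.", call. = FALSE)
  }
  if (length(cfg$date_range) != 2L || cfg$date_range[2] < cfg$date_range[1]) {
    stop("`date_range` must be two non-decreasing dates.", call. = FALSE)
  }
  invisible(cfg)
}

check_prob_vector <- function(p, len, name) {
  if (!is.numeric(p) || length(p) != len || any(p < 0)) {
    stop("`", name, "` must be ", len, " non-negative probabilities.",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("`", name, "` must sum to 1 (got ", format(sum(p)), ").",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n")
  cat("  n_respondents:", x$n_respondents, " seed:", x$seed, "\n")
  cat("  delay ORs (trust/freq/chronic):",
      paste(round(exp(c(x$beta_trust, x$beta_freq, x$beta_chronic)), 3),
            collapse = " / "), "\n")
  cat("  target delay rate:", x$target_delay_rate,
      " chronic prevalence:", x$chronic_prev, "\n")
  cat("  trust-frequency slope:", x$path_a_slope,
      " (noise sd ", x$path_a_noise_sd, ")\n", sep = "")
  cat("  dirty fraction:", x$dirty_fraction, "\n")
  invisible(x)
}
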