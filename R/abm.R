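#' Configuration for the trust-delay agent-based model
#'
#' Parameters of the daily simulation of trust-delay feedback on a
#' small-world network. Each agent carries a trust and usage-frequency score
#' on a 1-5 scale plus a chronic-disease flag; every day it computes a delay
#' probability from the survey-fitted logistic model, makes a probabilistic
#' delay decision, and updates its scores from the personal outcome
#' (delaying erodes trust by `delta_delay_trust` and frequency by
#' `delta_delay_freq`; not delaying raises trust by `delta_nodelay_trust`),
#' from peers (attraction toward the neighbourhood mean trust with gain
#' `peer_gain`; a penalty `peer_delay_penalty` when more than
#' `peer_delay_threshold` of neighbours delayed today), and from a global
#' daily erosion `trust_decay`; scores are then clamped to \[1, 5\].
#'
#' The peer gain, peer delay penalty, and daily decay are not identified by
#' the survey itself; they were calibrated once, by grid search, against the
#' baseline trajectory anchors (day-1 delay near 10.6%, day-14 delay near
#' 9.5%, day-14 mean trust near 1.49) and then frozen as the defaults below.
#' See the package vignette for the calibration grid and rationale.
#'
#' @param n_agents Number of agents.
#' @param degree_k Even lattice degree of the Watts-Strogatz network.
#' @param rewire_p Watts-Strogatz rewiring probability.
#' @param days Simulated days per trial.
#' @param trials Number of independent trials.
#' @param strategy One of `"baseline"`, `"broadcast"`, `"reward"`,
#'   `"rewire"`.
#' @param delta_delay_trust,delta_delay_freq Trust/frequency reduction after
#'   a personal delay.
#' @param delta_nodelay_trust Trust gain after a day without delay.
#' @param risk_threshold Baseline-risk cutoff (strict `>`) above which
#'   agents receive the structural-vulnerability reduction at
#'   initialization.
#' @param init_reduction Size of that initial trust/frequency reduction.
#' @param broadcast_penalty Daily trust penalty under the broadcast
#'   strategy.
#' @param reward_magnitude Trust and frequency bonus under the reward
#'   strategy.
#' @param reward_interval_days Reward cadence; agents with no delay within
#'   the current window are rewarded.
#' @param rewire_interval_days Rewiring cadence under the rewire strategy.
#' @param rewire_fraction Fraction of edges redirected per rewiring event.
#' @param peer_gain Gain of the attraction toward the neighbourhood mean
#'   trust.
#' @param peer_delay_penalty Trust penalty when neighbours delayed en masse.
#' @param peer_delay_threshold Fraction of delaying neighbours (strict `>`)
#'   that triggers the penalty.
#' @param trust_decay Global daily trust erosion.
#' @param init_trust_mean Optional target mean for the initial trust
#'   distribution (location shift then clamp to \[1, 5\]); `NULL` keeps the
#'   empirical initialization. Used by the sensitivity sweeps.
#' @param base_seed Base seed; trial `t` runs with seed `base_seed + t`.
#'
#' @return A list of class `"abm_config"`.
#' @export
abm_config <- function(n_agents = 2460L,
                       degree_k = 4L,
                       rewire_p = 0.2,
                       days = 14L,
                       trials = 100L,
                       strategy = c("baseline", "broadcast", "reward",
                                    "rewire"),
                       delta_delay_trust = 0.2,
                       delta_delay_freq = 0.3,
                       delta_nodelay_trust = 0.1,
                       risk_threshold = 0.20,
                       init_reduction = 1.0,
                       broadcast_penalty = 0.10,
                       reward_magnitude = 0.05,
                       reward_interval_days = 2L,
                       rewire_interval_days = 5L,
                       rewire_fraction = 0.10,
                       peer_gain = 0.05,
                       peer_delay_penalty = 0.10,
                       peer_delay_threshold = 0.5,
                       trust_decay = 0.125,
                       init_trust_mean = NULL,
                       base_seed = 1L) {
  strategy <- match.arg(strategy)
  cfg <- list(
    n_agents = as.integer(n_agents), degree_k = as.integer(degree_k),
    rewire_p = rewire_p, days = as.integer(days),
    trials = as.integer(trials), strategy = strategy,
    delta_delay_trust = delta_delay_trust,
    delta_delay_freq = delta_delay_freq,
    delta_nodelay_trust = delta_nodelay_trust,
    risk_threshold = risk_threshold, init_reduction = init_reduction,
    broadcast_penalty = broadcast_penalty,
    reward_magnitude = reward_magnitude,
    reward_interval_days = as.integer(reward_interval_days),
    rewire_interval_days = as.integer(rewire_interval_days),
    rewire_fraction = rewire_fraction,
    peer_gain = peer_gain, peer_delay_penalty = peer_delay_penalty,
    peer_delay_threshold = peer_delay_threshold,
    trust_decay = trust_decay,
    init_trust_mean = init_trust_mean,
    base_seed = as.integer(base_seed)
  )
  class(cfg) <- "abm_config"
  validate_abm_config(cfg)
  cfg
}

validate_abm_config <- function(cfg) {
  if (cfg$days < 1L) stop("`days` must be >= 1.", call. = FALSE)
  if (cfg$trials < 1L) stop("`trials` must be >= 1.", call. = FALSE)
  if (cfg$degree_k >= cfg$n_agents) {
    stop("`degree_k` must be smaller than `n_agents`.", call. = FALSE)
  }
  deltas <- c(cfg$delta_delay_trust, cfg$delta_delay_freq,
              cfg$delta_nodelay_trust, cfg$broadcast_penalty,
              cfg$reward_magnitude, cfg$peer_gain, cfg$peer_delay_penalty,
              cfg$trust_decay)
  if (any(deltas < 0)) {
    stop("All update magnitudes must be non-negative.", call. = FALSE)
  }
  invisible(cfg)
}

#' Fit the delay model on the agent scale
#'
#' Fits the three-predictor logistic delay model (`delay ~ trust + frequency
#' + chronic`) with trust and usage frequency mapped onto the 1-5 scale the
#' simulation operates on (survey level 0, "never used", maps to 1). Because
#' the model is refit on the same scale the agents carry, the mean predicted
#' delay probability over the un-reduced population equals the observed
#' survey delay prevalence, which anchors the simulation's day-1 delay rate.
#'
#' @param records Survey records.
#' @param outcome Binary outcome column.
#' @return A `delay_fit` suitable for [initialize_agents()],
#'   [daily_step()], and [run_experiment()].
#' @export
fit_abm_model <- function(records, outcome = "delay") {
  mapped <- dplyr::mutate(records,
                          trust = pmax(1, .data$trust),
                          frequency = pmax(1, .data$frequency))
  fit_logistic(mapped, outcome, c("trust", "frequency", "chronic"))
}

#' Calibrated delay model on the agent scale
#'
#' Returns the generating logistic model of the synthetic survey, re-anchored
#' to the 1-5 agent scale: the configured trust/frequency/chronic log-odds
#' ratios are kept and the intercept is recalibrated (bisection) so that the
#' mean predicted delay probability over the mapped covariates equals the
#' configured target prevalence. Unlike [fit_abm_model()], which refits the
#' model to one realized outcome draw, this conditions the simulation on the
#' calibrated survey conditions themselves, so trajectory anchors do not
#' inherit the binomial noise of a single synthetic outcome draw.
#'
#' @param records Survey records supplying the covariate distribution.
#' @param config The [survey_config()] holding the generating coefficients
#'   and target delay rate.
#' @return A named coefficient vector (`b0`, `trust`, `frequency`,
#'   `chronic`) accepted by [initialize_agents()], [daily_step()], and
#'   [run_experiment()].
#' @export
calibrated_abm_model <- function(records, config = survey_config()) {
  mapped <- data.frame(trust = pmax(1, records$trust),
                       frequency = pmax(1, records$frequency),
                       chronic = records$chronic)
  coefs <- c(trust = config$beta_trust, frequency = config$beta_freq,
             chronic = config$beta_chronic)
  b0 <- calibrate_intercept(coefs, mapped, config$target_delay_rate)
  c(b0 = b0, coefs)
}

# Pull the (intercept, trust, frequency, chronic) coefficients from a fitted
# delay model, in the fixed order used by the fast per-day update.
abm_coefs <- function(fit) {
  if (is.numeric(fit)) {
    if (!all(c("b0", "trust", "frequency", "chronic") %in% names(fit))) {
      stop("Coefficient vector needs names b0, trust, frequency, chronic.",
           call. = FALSE)
    }
    return(fit[c("b0", "trust", "frequency", "chronic")])
  }
  stopifnot(inherits(fit, "delay_fit"))
  tt <- fit$terms
  need <- c("(Intercept)", "trust", "frequency", "chronic")
  if (!all(need %in% tt$term)) {
    stop("ABM requires a delay model with terms trust, frequency, chronic.",
         call. = FALSE)
  }
  stats::setNames(tt$estimate[match(need, tt$term)],
                  c("b0", "trust", "frequency", "chronic"))
}

#' Initialize agents from survey records
#'
#' Copies trust, usage frequency, and chronic status from the records onto
#' the 1-5 simulation scale (survey level 0 maps to 1), optionally shifts
#' the trust distribution to a target mean (sensitivity sweeps), computes
#' each agent's baseline delay risk from the fitted logistic model on the
#' mapped values, and applies the structural-vulnerability rule: agents with
#' baseline risk strictly above `risk_threshold` have `init_reduction`
#' subtracted from trust and frequency (clamped at 1).
#'
#' @param records Survey records (one row per agent).
#' @param fit A `delay_fit` with terms trust, frequency, chronic (typically
#'   from [fit_abm_model()]), or a named coefficient vector with elements
#'   `b0`, `trust`, `frequency`, `chronic`.
#' @param config An [abm_config()].
#' @return A tibble of agents: `id`, `trust`, `frequency`, `chronic`,
#'   `baseline_risk` (pre-reduction), `high_risk`.
#' @export
initialize_agents <- function(records, fit, config = abm_config()) {
  if (nrow(records) != config$n_agents) {
    stop("`records` has ", nrow(records), " rows but `n_agents` is ",
         config$n_agents, ".", call. = FALSE)
  }
  cf <- abm_coefs(fit)
  trust <- pmax(1, as.numeric(records$trust))
  freq <- pmax(1, as.numeric(records$frequency))
  if (!is.null(config$init_trust_mean)) {
    trust <- pmin(5, pmax(1, trust + (config$init_trust_mean - mean(trust))))
  }
  chronic <- as.numeric(records$chronic)
  risk <- stats::plogis(cf["b0"] + cf["trust"] * trust +
                          cf["frequency"] * freq + cf["chronic"] * chronic)
  high <- risk > config$risk_threshold
  trust[high] <- pmax(1, trust[high] - config$init_reduction)
  freq[high] <- pmax(1, freq[high] - config$init_reduction)
  tibble::tibble(
    id = seq_len(nrow(records)),
    trust = trust,
    frequency = freq,
    chronic = chronic,
    baseline_risk = as.numeric(risk),
    high_risk = as.logical(high),
    window_delays = 0L,
    delayed_today = FALSE
  )
}

#' Advance the simulation by one day
#'
#' Executes one daily cycle: each agent's delay probability is computed from
#' its current trust, frequency, and chronic status via the fitted logistic
#' model and a Bernoulli delay decision is drawn; daily statistics are
#' recorded on the start-of-day trust values and today's decisions; then
#' updates are applied in fixed order -- personal outcome, peer terms
#' (synchronous, using start-of-day trust and today's decisions), global
#' decay, the active intervention, and finally clamping to \[1, 5\].
#'
#' @param agents Agent tibble from [initialize_agents()].
#' @param network A `trust_network`.
#' @param fit A `delay_fit` (or the coefficient vector from it).
#' @param config An [abm_config()].
#' @param day Day index (1-based).
#' @return A list with `agents` (updated), `network` (updated under the
#'   rewire strategy), and `stats` (one-row tibble of daily statistics).
#' @export
daily_step <- function(agents, network, fit, config, day) {
  cf <- if (inherits(fit, "delay_fit")) abm_coefs(fit) else fit
  t0 <- agents$trust
  f0 <- agents$frequency
  p <- stats::plogis(cf["b0"] + cf["trust"] * t0 + cf["frequency"] * f0 +
                       cf["chronic"] * agents$chronic)
  delayed <- stats::runif(length(t0)) < p

  stats <- tibble::tibble(
    day = day,
    delay_rate = mean(delayed),
    n_delayed = sum(delayed),
    mean_trust = mean(t0),
    mean_trust_highrisk = mean(t0[agents$high_risk]),
    mean_trust_lowrisk = mean(t0[!agents$high_risk])
  )

  # (1) personal outcome
  trust <- t0 - config$delta_delay_trust * delayed +
    config$delta_nodelay_trust * (!delayed)
  freq <- f0 - config$delta_delay_freq * delayed

  # (2) peer terms: synchronous, on start-of-day trust / today's decisions
  if (config$peer_gain > 0 || config$peer_delay_penalty > 0) {
    deg <- network$deg
    safe_deg <- pmax(deg, 1)
    nbr_trust <- as.numeric(network$adj %*% t0) / safe_deg
    nbr_delay <- as.numeric(network$adj %*% delayed) / safe_deg
    has_nbr <- deg > 0
    trust <- trust + config$peer_gain * (nbr_trust - t0) * has_nbr
    trust <- trust - config$peer_delay_penalty *
      (has_nbr & nbr_delay > config$peer_delay_threshold)
  }

  # (3) global decay
  trust <- trust - config$trust_decay

  agents$trust <- trust
  agents$frequency <- freq
  agents$delayed_today <- delayed
  agents$window_delays <- agents$window_delays + delayed

  # (4) intervention hook
  if (config$strategy == "broadcast") {
    agents <- apply_broadcast(agents, config)
  } else if (config$strategy == "reward") {
    agents <- apply_reward(agents, config, day)
  } else if (config$strategy == "rewire") {
    if (day %% config$rewire_interval_days == 0L) {
      network <- rewire_to_top_decile(network, agents$trust,
                                      config$rewire_fraction)
    }
  }

  # (5) clamp
  agents$trust <- pmin(5, pmax(1, agents$trust))
  agents$frequency <- pmin(5, pmax(1, agents$frequency))

  list(agents = agents, network = network, stats = stats)
}

#' Broadcast intervention: daily trust-eroding message
#'
#' Subtracts a fixed penalty from every agent's trust (clamping is deferred
#' to the end of the daily step).
#'
#' @param agents Agent tibble.
#' @param config An [abm_config()].
#' @return Updated agent tibble.
#' @export
apply_broadcast <- function(agents, config) {
  if (config$broadcast_penalty < 0) {
    stop("`broadcast_penalty` must be non-negative.", call. = FALSE)
  }
  agents$trust <- agents$trust - config$broadcast_penalty
  agents
}

#' Reward intervention: bonus for consistently timely care
#'
#' On days divisible by `reward_interval_days`, agents with no delay during
#' the current reward window (the last `reward_interval_days` days,
#' including today) gain `reward_magnitude` on both trust and frequency; the
#' window counter then resets.
#'
#' @param agents Agent tibble (with `window_delays` already including
#'   today's decision).
#' @param config An [abm_config()].
#' @param day Day index.
#' @return Updated agent tibble.
#' @export
apply_reward <- function(agents, config, day) {
  if (day %% config$reward_interval_days == 0L) {
    good <- agents$window_delays == 0L
    agents$trust[good] <- agents$trust[good] + config$reward_magnitude
    agents$frequency[good] <- agents$frequency[good] + config$reward_magnitude
    agents$window_delays <- 0L
  }
  agents
}

#' Rewire intervention: redirect edges toward opinion leaders
#'
#' On days divisible by `rewire_interval_days`, a fraction of randomly
#' chosen edges each have one randomly chosen endpoint re-attached to an
#' agent sampled uniformly from the top trust decile (ties broken by lowest
#' id); self-loops and duplicates are avoided and the edge count is
#' conserved.
#'
#' @param network A `trust_network`.
#' @param agents Agent tibble (current trust is used to rank agents).
#' @param config An [abm_config()].
#' @param day Day index.
#' @return The (possibly) rewired `trust_network`.
#' @export
apply_rewire <- function(network, agents, config, day) {
  if (day %% config$rewire_interval_days != 0L) return(network)
  rewire_to_top_decile(network, agents$trust, config$rewire_fraction)
}

#' Run a multi-trial simulation experiment
#'
#' Runs `trials` independent trials of the daily simulation. Each trial `t`
#' reseeds the RNG with `base_seed + t`, rebuilds the network, and
#' re-initializes the agents, so a full experiment is reproducible from the
#' configuration alone. Daily population statistics are averaged over
#' trials with standard errors.
#'
#' @param records Survey records (one per agent).
#' @param fit A `delay_fit` with terms trust, frequency, chronic.
#' @param config An [abm_config()].
#' @return An object of class `"trust_trajectory"`: `by_day` (tibble of
#'   trial-mean daily statistics with standard errors), `pooled` (total
#'   delays and agent-days across all trials and days, for strategy
#'   comparison), `config`, and `strategy`.
#' @export
#' @examples
#' pop <- generate_population(survey_config(n_respondents = 200, seed = 1))
#' fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
#' cfg <- abm_config(n_agents = 200, trials = 2, days = 3)
#' run_experiment(pop, fit, cfg)$by_day
run_experiment <- function(records, fit, config = abm_config()) {
  validate_abm_config(config)
  cf <- abm_coefs(fit)
  nt <- config$trials
  nd <- config$days
  delay_rate <- matrix(NA_real_, nt, nd)
  mean_trust <- matrix(NA_real_, nt, nd)
  mt_high <- matrix(NA_real_, nt, nd)
  mt_low <- matrix(NA_real_, nt, nd)
  n_delayed <- matrix(NA_real_, nt, nd)

  for (t in seq_len(nt)) {
    set.seed(config$base_seed + t)
    net <- build_network(config$n_agents, config$degree_k, config$rewire_p)
    agents <- initialize_agents(records, fit, config)
    for (d in seq_len(nd)) {
      step <- daily_step(agents, net, cf, config, d)
      agents <- step$agents
      net <- step$network
      delay_rate[t, d] <- step$stats$delay_rate
      n_delayed[t, d] <- step$stats$n_delayed
      mean_trust[t, d] <- step$stats$mean_trust
      mt_high[t, d] <- step$stats$mean_trust_highrisk
      mt_low[t, d] <- step$stats$mean_trust_lowrisk
    }
  }

  col_se <- function(m) {
    if (nt == 1L) rep(NA_real_, ncol(m))
    else apply(m, 2, stats::sd) / sqrt(nt)
  }
  dr_se <- col_se(delay_rate)
  mt_se <- col_se(mean_trust)
  by_day <- tibble::tibble(
    day = seq_len(nd),
    delay_rate = colMeans(delay_rate),
    delay_rate_se = dr_se,
    mean_trust = colMeans(mean_trust),
    mean_trust_se = mt_se,
    mean_trust_highrisk = colMeans(mt_high),
    mean_trust_lowrisk = colMeans(mt_low)
  )
  structure(
    list(
      by_day = by_day,
      pooled = c(delays = sum(n_delayed),
                 agent_days = as.numeric(nt) * nd * config$n_agents),
      trials = nt,
      strategy = config$strategy,
      config = config
    ),
    class = "trust_trajectory"
  )
}

#' @export
print.trust_trajectory <- function(x, ...) {
  cat("<trust_trajectory> strategy =", x$strategy, "|", x$trials,
      "trials x", nrow(x$by_day), "days\n")
  d1 <- x$by_day[1, ]
  dl <- x$by_day[nrow(x$by_day), ]
  cat(sprintf("  delay rate: %.1f%% (day 1) -> %.1f%% (day %d)\n",
              100 * d1$delay_rate, 100 * dl$delay_rate, dl$day))
  cat(sprintf("  mean trust: %.2f (day 1) -> %.2f (day %d)\n",
              d1$mean_trust, dl$mean_trust, dl$day))
  invisible(x)
}

#' @export
tidy.trust_trajectory <- function(x, ...) {
  dplyr::mutate(x$by_day, strategy = x$strategy, .before = 1)
}

#' Trajectory plots for a simulation experiment
#'
#' Shows the trial-mean daily delay rate, overall mean trust, and mean trust
#' by baseline-risk stratum.
#'
#' @param object A `trust_trajectory`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.trust_trajectory <- function(object, ...) {
  d <- object$by_day
  long <- tidyr::pivot_longer(
    dplyr::transmute(
      d, day = .data$day,
      `Delay rate` = .data$delay_rate,
      `Mean trust` = .data$mean_trust,
      `Trust (high risk)` = .data$mean_trust_highrisk,
      `Trust (low risk)` = .data$mean_trust_lowrisk
    ),
    -"day", names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Day", y = NULL,
                  title = paste("Strategy:", object$strategy)) +
    ggplot2::theme_minimal()
}

#' Compare intervention strategies on pooled agent-day outcomes
#'
#' Pools the agent-day delay indicators of each experiment arm (agent x day
#' x trial) and fits a logistic regression of delay on strategy indicator
#' variables with the baseline arm as reference, via the aggregated binomial
#' likelihood (identical maximum-likelihood estimates to the fully expanded
#' agent-day regression). Returns one odds ratio with Wald 95% CI per
#' non-baseline strategy.
#'
#' @param arms Named list of `trust_trajectory` objects; must contain an
#'   element named `"baseline"`.
#' @return A tibble with columns `strategy`, `odds.ratio`, `conf.low`,
#'   `conf.high`, `p.value`, `delays`, `agent_days`.
#' @export
compare_strategies <- function(arms) {
  if (!"baseline" %in% names(arms)) {
    stop("`arms` must contain a \"baseline\" element.", call. = FALSE)
  }
  counts <- purrr::map_dfr(names(arms), function(nm) {
    tibble::tibble(
      strategy = nm,
      delays = arms[[nm]]$pooled[["delays"]],
      agent_days = arms[[nm]]$pooled[["agent_days"]]
    )
  })
  counts$strategy <- stats::relevel(factor(counts$strategy),
                                    ref = "baseline")
  gfit <- stats::glm(
    cbind(delays, agent_days - delays) ~ strategy,
    family = stats::binomial(), data = counts
  )
  beta <- stats::coef(gfit)
  se <- sqrt(diag(stats::vcov(gfit)))
  keep <- names(beta) != "(Intercept)"
  tibble::tibble(
    strategy = sub("^strategy", "", names(beta)[keep]),
    odds.ratio = exp(unname(beta[keep])),
    conf.low = exp(unname(beta[keep]) - 1.96 * unname(se[keep])),
    conf.high = exp(unname(beta[keep]) + 1.96 * unname(se[keep])),
    p.value = 2 * stats::pnorm(-abs(unname(beta[keep]) / unname(se[keep]))),
    delays = counts$delays[match(sub("^strategy", "", names(beta)[keep]),
                                 counts$strategy)],
    agent_days = counts$agent_days[match(sub("^strategy", "",
                                             names(beta)[keep]),
                                         counts$strategy)]
  )
}
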