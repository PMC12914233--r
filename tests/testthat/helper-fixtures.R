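# Shared fixtures, all generated in code.

default_pop <- function(n = 2460, seed = 1, ...) {
  generate_population(survey_config(n_respondents = n, seed = seed, ...))
}

# A coefficient vector usable wherever a fitted delay model is expected in
# the simulator (initialize_agents, daily_step, run_experiment).
coef_vec <- function(b0 = -3, trust = log(1.09), frequency = log(1.40),
                     chronic = log(1.42)) {
  c(b0 = b0, trust = trust, frequency = frequency, chronic = chronic)
}

# Minimal agent records on the 1-5 scale.
agent_records <- function(trust, frequency = trust, chronic = 0) {
  n <- max(length(trust), length(frequency), length(chronic))
  tibble::tibble(
    id = seq_len(n),
    trust = rep_len(trust, n),
    frequency = rep_len(frequency, n),
    chronic = rep_len(chronic, n)
  )
}

# 2x2 exposure/outcome data with given cell counts:
# (exposed cases, exposed controls, unexposed cases, unexposed controls)
two_by_two <- function(a, b, c, d) {
  tibble::tibble(
    exposed = c(rep(1, a + b), rep(0, c + d)),
    case = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
}
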