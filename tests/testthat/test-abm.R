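test_that("small-world construction yields a simple graph with n*k/2 edges", {
  # no rewiring: pure ring lattice, all degrees exactly k
  net <- build_network(10, 4, 0)
  expect_equal(nrow(net$edges), 20)
  expect_true(all(net$deg == 4))

  # full rewiring: edge count conserved, no self-loops, no duplicates
  net1 <- build_network(10, 4, 1, seed = 3)
  expect_equal(nrow(net1$edges), 20)
  expect_true(all(net1$edges[, 1] != net1$edges[, 2]))
  keys <- paste(pmin(net1$edges[, 1], net1$edges[, 2]),
                pmax(net1$edges[, 1], net1$edges[, 2]))
  expect_equal(anyDuplicated(keys), 0)

  big <- build_network(2460, 4, 0.2, seed = 1)
  expect_equal(nrow(big$edges), 4920)
  expect_equal(mean(big$deg), 4)

  expect_error(build_network(10, 3, 0.2), "even")
  expect_error(build_network(4, 6, 0.2), "0 < k < n")
  expect_error(build_network(10, 4, 1.5), "\\[0, 1\\]")
})

test_that("agent initialization maps scales and applies the vulnerability rule", {
  # b0 chosen so that trust=3,freq=3,chronic=0 has risk 0.25 > 0.20
  cf <- coef_vec(b0 = qlogis(0.25) - 3 * log(1.09) - 3 * log(1.40))
  rec <- agent_records(trust = c(3, 0, 1, 1), frequency = c(3, 0, 1, 1))
  cfg <- abm_config(n_agents = 4, degree_k = 2)
  ag <- initialize_agents(rec, cf, cfg)
  expect_equal(ag$baseline_risk[1], 0.25, tolerance = 1e-12)
  expect_equal(ag$trust[1], 2)      # 1-point reduction
  expect_equal(ag$frequency[1], 2)
  expect_equal(ag$trust[2], 1)      # survey level 0 maps to scale floor

  # risk exactly at the threshold: strict inequality, no reduction
  cf2 <- coef_vec(b0 = qlogis(0.20) - 3 * log(1.09) - 3 * log(1.40))
  ag2 <- initialize_agents(agent_records(trust = rep(3, 4)), cf2, cfg)
  expect_equal(ag2$trust, rep(3, 4))
  expect_false(any(ag2$high_risk))

  expect_error(initialize_agents(rec, cf, abm_config(n_agents = 5)),
               "rows")
})

test_that("daily updates follow the personal-outcome rules and clamp to [1,5]", {
  net <- build_network(4, 2, 0)
  # init_reduction disabled so that agents start exactly at the recorded
  # scores regardless of their predicted risk
  cfg0 <- abm_config(n_agents = 4, degree_k = 2, peer_gain = 0,
                     peer_delay_penalty = 0, trust_decay = 0,
                     init_reduction = 0)

  # certain delay: b0 huge
  ag <- initialize_agents(agent_records(trust = rep(3, 4)),
                          coef_vec(b0 = 50), cfg0)
  step <- daily_step(ag, net, coef_vec(b0 = 50), cfg0, day = 1)
  expect_equal(step$stats$delay_rate, 1)
  expect_equal(step$agents$trust, rep(2.8, 4))
  expect_equal(step$agents$frequency, rep(2.7, 4))

  # certain non-delay: trust up 0.1, frequency unchanged
  ag2 <- initialize_agents(agent_records(trust = rep(3, 4)),
                           coef_vec(b0 = -50), cfg0)
  step2 <- daily_step(ag2, net, coef_vec(b0 = -50), cfg0, day = 1)
  expect_equal(step2$stats$delay_rate, 0)
  expect_equal(step2$agents$trust, rep(3.1, 4))
  expect_equal(step2$agents$frequency, rep(3, 4))

  # clamping at the ceiling
  ag5 <- initialize_agents(agent_records(trust = rep(5, 4)),
                           coef_vec(b0 = -50), cfg0)
  step5 <- daily_step(ag5, net, coef_vec(b0 = -50), cfg0, day = 1)
  expect_equal(step5$agents$trust, rep(5, 4))

  # statistics are recorded on start-of-day trust
  expect_equal(step$stats$mean_trust, 3)
})

test_that("the broadcast penalty subtracts a fixed daily amount", {
  cfg <- abm_config(strategy = "broadcast", broadcast_penalty = 0.10)
  ag <- tibble::tibble(trust = c(3, 1), frequency = c(3, 3))
  out <- apply_broadcast(ag, cfg)
  expect_equal(out$trust, c(2.9, 0.9))  # clamp is deferred to the daily step

  cfg0 <- abm_config(strategy = "broadcast", broadcast_penalty = 0)
  expect_equal(apply_broadcast(ag, cfg0)$trust, ag$trust)
})

test_that("rewards apply only on cycle days to agents with a clean window", {
  cfg <- abm_config(strategy = "reward", reward_magnitude = 0.05,
                    reward_interval_days = 2)
  ag <- tibble::tibble(trust = c(3, 3), frequency = c(3, 3),
                       window_delays = c(0L, 1L))
  # off-cycle day: nothing happens
  out3 <- apply_reward(ag, cfg, day = 3)
  expect_equal(out3$trust, c(3, 3))
  # cycle day: only the agent with no delays in the window is rewarded
  out4 <- apply_reward(ag, cfg, day = 4)
  expect_equal(out4$trust, c(3.05, 3))
  expect_equal(out4$frequency, c(3.05, 3))
  expect_equal(out4$window_delays, c(0L, 0L))  # window resets
})

test_that("rewiring conserves edges and terminates under tied trust", {
  net <- build_network(12, 4, 0.2, seed = 5)
  ag <- tibble::tibble(trust = rep(2, 12))
  cfg <- abm_config(n_agents = 12, strategy = "rewire",
                    rewire_interval_days = 5)
  # off-cycle day: untouched
  expect_identical(apply_rewire(net, ag, cfg, day = 4)$edges, net$edges)
  # cycle day, all-tied trust: terminates, edge count conserved, simple graph
  set.seed(1)
  out <- apply_rewire(net, ag, cfg, day = 5)
  expect_equal(nrow(out$edges), nrow(net$edges))
  expect_true(all(out$edges[, 1] != out$edges[, 2]))
  keys <- paste(pmin(out$edges[, 1], out$edges[, 2]),
                pmax(out$edges[, 1], out$edges[, 2]))
  expect_equal(anyDuplicated(keys), 0)

  # heterogeneous trust: rewired endpoints attach to the top decile
  set.seed(2)
  net2 <- build_network(50, 4, 0.2)
  ag2 <- tibble::tibble(trust = seq(1, 5, length.out = 50))
  cfg2 <- abm_config(n_agents = 50, strategy = "rewire",
                     rewire_interval_days = 1, rewire_fraction = 0.5)
  out2 <- apply_rewire(net2, ag2, cfg2, day = 1)
  top <- order(-ag2$trust)[1:5]
  expect_gt(sum(out2$deg[top]), sum(net2$deg[top]))
})

test_that("trajectories are reproducible and respect the score bounds daily", {
  pop <- default_pop(n = 300, seed = 6)
  fit <- fit_abm_model(pop)
  cfg <- abm_config(n_agents = 300, trials = 2, days = 8, base_seed = 11)
  tr1 <- run_experiment(pop, fit, cfg)
  tr2 <- run_experiment(pop, fit, cfg)
  expect_identical(tr1$by_day, tr2$by_day)
  expect_identical(tr1$pooled, tr2$pooled)

  # bounds asserted after every daily step
  set.seed(99)
  net <- build_network(300, 4, 0.2)
  agents <- initialize_agents(pop, fit, cfg)
  for (d in 1:8) {
    st <- daily_step(agents, net, fit, cfg, d)
    agents <- st$agents; net <- st$network
    expect_true(all(agents$trust >= 1 & agents$trust <= 5))
    expect_true(all(agents$frequency >= 1 & agents$frequency <= 5))
  }
  expect_equal(nrow(net$edges), 600)  # conservation across the run
})

test_that("null dynamics leave the delay trajectory flat", {
  pop <- default_pop(n = 2000, seed = 15)
  fit <- fit_abm_model(pop)
  cfg <- abm_config(n_agents = 2000, trials = 10, days = 10,
                    delta_delay_trust = 0, delta_delay_freq = 0,
                    delta_nodelay_trust = 0, peer_gain = 0,
                    peer_delay_penalty = 0, trust_decay = 0)
  tr <- run_experiment(pop, fit, cfg)
  agents <- initialize_agents(pop, fit, cfg)
  cf <- trustdelay:::abm_coefs(fit)
  p0 <- mean(plogis(cf["b0"] + cf["trust"] * agents$trust +
                      cf["frequency"] * agents$frequency +
                      cf["chronic"] * agents$chronic))
  mc_se <- sqrt(p0 * (1 - p0) / (2000 * 10))
  expect_true(all(abs(tr$by_day$delay_rate - p0) < 4 * mc_se))
  expect_true(all(tr$by_day$mean_trust == tr$by_day$mean_trust[1]))
})

test_that("raising initial trust weakly increases the day-1 delay rate", {
  pop <- default_pop(n = 1500, seed = 16)
  fit <- fit_abm_model(pop)
  cfg <- abm_config(n_agents = 1500, trials = 5, days = 1)
  base <- run_experiment(pop, fit, cfg)
  cfg_hi <- cfg
  agents <- initialize_agents(pop, fit, cfg)
  cfg_hi$init_trust_mean <- mean(pmax(1, pop$trust)) + 1
  hi <- run_experiment(pop, fit, cfg_hi)
  expect_gte(hi$by_day$delay_rate[1], base$by_day$delay_rate[1])
})

test_that("strategy comparison recovers a null and requires a baseline arm", {
  pop <- default_pop(n = 400, seed = 17)
  fit <- fit_abm_model(pop)
  cfg <- abm_config(n_agents = 400, trials = 3, days = 5)
  a <- run_experiment(pop, fit, cfg)
  b <- run_experiment(pop, fit, cfg)  # identical config and seeds
  comp <- compare_strategies(list(baseline = a, clone = b))
  expect_equal(comp$odds.ratio, 1, tolerance = 1e-10)

  expect_error(compare_strategies(list(broadcast = a)), "baseline")
})

test_that("broadcast erodes trust below baseline from day 2 onward", {
  pop <- default_pop(n = 1000, seed = 18)
  fit <- fit_abm_model(pop)
  cfg_b <- abm_config(n_agents = 1000, trials = 5, days = 8,
                      strategy = "broadcast")
  cfg_0 <- abm_config(n_agents = 1000, trials = 5, days = 8)
  tb <- run_experiment(pop, fit, cfg_b)$by_day
  t0 <- run_experiment(pop, fit, cfg_0)$by_day
  expect_true(all(tb$mean_trust[-1] < t0$mean_trust[-1]))
})
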