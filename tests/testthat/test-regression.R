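test_that("single-binary-predictor fit equals the closed-form 2x2 odds ratio", {
  # cross-product-ratio oracle: OR = (a*d)/(b*c)
  cases <- list(c(10, 20, 30, 40), c(25, 75, 10, 90), c(5, 45, 50, 50))
  for (cc in cases) {
    df <- two_by_two(cc[1], cc[2], cc[3], cc[4])
    oracle <- (cc[1] * cc[4]) / (cc[2] * cc[3])
    fit <- fit_logistic(df, "case", "exposed")
    est <- fit$terms$odds.ratio[fit$terms$term == "exposed"]
    expect_equal(est, oracle, tolerance = 1e-6)
  }
})

test_that("odds ratio equals exp(coefficient) and CIs bracket it", {
  pop <- default_pop(n = 1200, seed = 21)
  fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
  tt <- tidy(fit)
  expect_equal(tt$odds.ratio, exp(tt$estimate))
  expect_true(all(tt$conf.low < tt$odds.ratio & tt$odds.ratio < tt$conf.high))
  expect_true(fit$converged)
  expect_equal(glance(fit)$n_obs, 1200)
})

test_that("degenerate designs are flagged or rejected", {
  pop <- default_pop(n = 300, seed = 22)
  const <- dplyr::mutate(pop, z = 1)
  fit <- fit_logistic(const, "delay", c("trust", "z"))
  expect_true("z" %in% fit$zero_variance)
  expect_false(fit$converged)

  allsame <- dplyr::mutate(pop, delay = 0L)
  expect_error(fit_logistic(allsame, "delay", "trust"), "constant")
  expect_error(fit_logistic(pop, "nope", "trust"), "not found")
})

test_that("translation of a predictor changes only the intercept", {
  pop <- default_pop(n = 1500, seed = 23)
  f1 <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
  shifted <- dplyr::mutate(pop, trust = trust + 10)
  f2 <- fit_logistic(shifted, "delay", c("trust", "frequency", "chronic"))
  slope_terms <- c("trust", "frequency", "chronic")
  expect_equal(
    f1$terms$estimate[match(slope_terms, f1$terms$term)],
    f2$terms$estimate[match(slope_terms, f2$terms$term)],
    tolerance = 1e-6
  )
  i1 <- f1$terms$estimate[f1$terms$term == "(Intercept)"]
  i2 <- f2$terms$estimate[f2$terms$term == "(Intercept)"]
  expect_equal(i1, i2 + 10 * f2$terms$estimate[f2$terms$term == "trust"],
               tolerance = 1e-5)
})

test_that("mean fitted probability equals the observed outcome rate", {
  pop <- default_pop(n = 900, seed = 24)
  fit <- fit_logistic(pop, "delay", c("trust", "chronic"))
  expect_equal(mean(predict(fit)), mean(pop$delay), tolerance = 1e-8)
})

test_that("univariate screen returns one row per candidate in input order", {
  pop <- default_pop(seed = 25)
  scr <- univariate_screen(pop, c("trust", "frequency", "chronic"))
  expect_equal(scr$variable, c("trust", "frequency", "chronic"))
  # marginal trust effect includes the mediated path, so OR > 1
  expect_gt(scr$odds.ratio[scr$variable == "trust"], 1)

  expect_equal(nrow(univariate_screen(pop, character())), 0)

  degen <- dplyr::mutate(pop, z = 2)
  scr2 <- univariate_screen(degen, c("trust", "z"))
  expect_equal(scr2$note, c("ok", "zero_variance"))
  expect_true(is.na(scr2$odds.ratio[2]))
})

test_that("hierarchical models nest and their likelihood is non-decreasing", {
  pop <- default_pop(seed = 26)
  hm <- hierarchical_models(pop)
  expect_named(hm, paste0("model", 1:4))
  ll <- vapply(hm, function(f) glance(f)$logLik, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
  # chronic effect direction is stable across adjustment sets
  or_chronic <- vapply(hm, function(f) {
    f$terms$odds.ratio[f$terms$term == "chronic"]
  }, numeric(1))
  expect_true(all(or_chronic > 1))
  # the fully adjusted model keeps frequency as the strongest predictor
  m4 <- tidy(hm$model4)
  or4 <- m4$odds.ratio[match(c("trust", "frequency", "chronic"), m4$term)]
  expect_equal(which.max(or4), 2L)

  expect_error(hierarchical_models(pop[, setdiff(names(pop), "exposure")]),
               "exposure")
})

test_that("stratified analysis fits the same model per stratum", {
  pop <- default_pop(seed = 27)
  res <- stratified_analysis(pop, stratify_period(), "delay",
                             c("trust", "frequency", "chronic"))
  expect_setequal(unique(res$stratum), c("pre", "post"))
  # frequency ORs agree across the date split (no generated period effect)
  fr <- res[res$term == "frequency", ]
  ci_overlap <- fr$conf.low[1] < fr$conf.high[2] &
    fr$conf.low[2] < fr$conf.high[1]
  expect_true(ci_overlap)

  # a stratifier putting everything in one group is an error
  expect_error(
    stratified_analysis(pop, function(r) rep("all", nrow(r))),
    "fewer than 2"
  )
})

test_that("exposure strata show overlapping trust CIs without a generated interaction", {
  hits <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    pop <- default_pop(n = 1800, seed = 300 + s)
    res <- stratified_analysis(pop, stratify_exposure(), "delay",
                               c("trust", "frequency", "chronic"))
    tr <- res[res$term == "trust", ]
    if (nrow(tr) == 2 && !anyNA(tr$conf.low) &&
        tr$conf.low[1] < tr$conf.high[2] && tr$conf.low[2] < tr$conf.high[1]) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("interaction model includes the product term once and emits a grid", {
  pop <- default_pop(seed = 28)
  im <- interaction_model(pop, "trust",
                          function(r) as.numeric(r$exposure > 2))
  expect_equal(sum(tidy(im)$term == ".interaction"), 1)
  expect_equal(nrow(im$interaction), 1)
  expect_true(all(c(".moderator", "pred_prob") %in% names(im$pred_grid)))
  expect_true(all(im$pred_grid$pred_prob > 0 & im$pred_grid$pred_prob < 1))

  expect_error(
    interaction_model(pop, "trust", function(r) rep(1, nrow(r))),
    "constant"
  )
  expect_error(
    interaction_model(pop, "trust", function(r) r$exposure),
    "binary"
  )
})

test_that("a generated trust-by-moderator interaction is detected with power", {
  # inject a log-OR 0.5 interaction into the delay outcome and check the
  # interaction CI excludes 1 in most seeds; without injection the CI covers
  # 1 in most seeds
  detect <- 0; cover_null <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    pop <- default_pop(seed = 600 + s)
    mod <- as.numeric(pop$exposure > 2)
    # null data
    im0 <- interaction_model(pop, "trust", function(r) mod)
    if (im0$interaction$conf.low <= 1 && im0$interaction$conf.high >= 1) {
      cover_null <- cover_null + 1
    }
    # re-draw delay with an interaction term added
    eta <- qlogis(predict(fit_logistic(pop, "delay",
                                       c("trust", "frequency", "chronic")),
                          pop)) + 0.5 * pop$trust * mod
    set.seed(s)
    pop$delay <- as.integer(runif(nrow(pop)) < plogis(eta))
    im1 <- interaction_model(pop, "trust", function(r) mod)
    if (im1$interaction$conf.low > 1 || im1$interaction$conf.high < 1) {
      detect <- detect + 1
    }
  }
  expect_gte(cover_null / n_seeds, 0.9)
  expect_gte(detect / n_seeds, 0.8)
})

test_that("Wald CIs attain nominal coverage of a generating odds ratio", {
  n_seeds <- 200
  covered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    pop <- default_pop(seed = 1000 + s)
    fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
    tt <- fit$terms[fit$terms$term == "frequency", ]
    covered[s] <- tt$conf.low <= 1.40 && 1.40 <= tt$conf.high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
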