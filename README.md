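# trustdelay

Trust in AI-generated health advice cuts both ways: it draws people into
digital self-management, but heavy reliance on reassuring machine advice can
postpone a visit to an actual clinician — especially for people with chronic
conditions. `trustdelay` is an R package for studying that trade-off
end-to-end. It is aimed at biostatisticians and computational epidemiologists
who want a fully reproducible, survey-calibrated pipeline from individual
level associations to population-level intervention simulation.

The package has three layers:

1. **A calibrated synthetic survey generator.** Respondent records carry an
   AI-trust score `T` on 0–5 (0 = never used AI advice), a usage-frequency
   score `F` on 0–5, a chronic-disease flag `C`, demographics, and a binary
   care-delay outcome `D` drawn from the generating model

   `logit P(D = 1) = β₀ + βT·T + βF·F + βC·C`

   with odds ratios exp(βT) = 1.09, exp(βF) = 1.40, exp(βC) = 1.42 and β₀
   calibrated by bisection so the marginal delay prevalence is 11.6%.
   Frequency is linked to trust by `F = round(clamp(0.5754·T + ε, 0, 5))`,
   with the hard consistency rule `T = 0 ⇒ F = 0`. The data-cleaning rules
   of a real web survey (sub-90-second completions, duplicates, missing
   values, logical inconsistencies) are implemented in `apply_exclusions()`.

2. **The statistical analyses.** Logistic regression with Wald inference
   (`fit_logistic()`, `univariate_screen()`, `hierarchical_models()`,
   `stratified_analysis()`, `interaction_model()`); Baron–Kenny mediation of
   trust → frequency → delay with the Sobel test and a 500-replicate
   nonparametric bootstrap of the indirect effect `a·b`
   (`estimate_paths()`, `sobel_test()`, `bootstrap_indirect()`); and
   six counterfactual scenarios of predicted delay probability
   (`simulate_scenarios()`).

3. **An agent-based simulator.** 2,460 agents on a Watts–Strogatz
   small-world network (mean degree 4, rewiring probability 0.2) carry
   trust/frequency on a 1–5 scale. Each day an agent delays care with its
   model-predicted probability, then updates: delaying costs 0.2 trust and
   0.3 frequency, not delaying gains 0.1 trust; trust is attracted toward
   the neighbourhood mean, penalized when most neighbours delayed, and
   erodes by a daily decay; scores clamp to [1, 5]. Three interventions —
   daily trust-eroding *broadcast* messages, periodic *rewards* for timely
   care, and *rewiring* edges toward high-trust opinion leaders — are
   compared by pooled agent-day logistic regression
   (`run_experiment()`, `compare_strategies()`), plus one-way sensitivity
   sweeps (`sweep_parameter()`).

Everything is tibble-in/tibble-out, with `tidy()`/`glance()` methods and
`autoplot()` figures, and a one-call orchestration of the whole analysis in
`run_full_pipeline()`.

## Worked example

```r
library(trustdelay)

pop <- generate_population(survey_config(seed = 1))
fit <- fit_logistic(pop, "delay", c("trust", "frequency", "chronic"))
fit
#> <delay_fit> delay ~ trust + frequency + chronic
#>   n = 2460
#> # A tibble: 4 × 8
#>   term      estimate std.error statistic   p.value odds.ratio conf.low conf.high
#> 1 (Interce…  -2.82      0.123     -23.0  3.00e-117     0.0594   0.0467    0.0756
#> 2 trust       0.0945    0.0446      2.12 3.42e-  2     1.10     1.01      1.20
#> 3 frequency   0.283     0.0437      6.47 9.93e- 11     1.33     1.22      1.45
#> 4 chronic     0.378     0.134       2.81 4.95e-  3     1.46     1.12      1.90
```

One synthetic draw of 2,460 respondents recovers the generating odds ratios
(1.09 / 1.40 / 1.42) within sampling error: each unit of trust raises the
odds of delaying care by ~10%, each frequency level by ~33%, chronic disease
by ~46%.

```r
med <- bootstrap_indirect(pop, n_boot = 500, seed = 2)
med
#> <mediation_result> trust -> frequency -> delay
#>   a        = 0.5828 (SE 0.0139)
#>   b        = 0.2813 (SE 0.0439)  [log-odds]
#>   indirect = 0.1639 (OR 1.178)
#>   c        = 0.2651   c' = 0.0965
#>   Sobel z = 6.337, p = 2.34e-10
#>   bootstrap (n=500): mean 0.1619, 95% CI [0.1159, 0.2114], p < 2.22e-16
```

Trust raises usage frequency (path *a* ≈ 0.58 frequency units per trust
unit), frequency raises delay (path *b*, log-odds), and the indirect effect
`a·b` is strongly bootstrap-significant — partial mediation, since the
direct effect *c′* stays positive.

```r
traj <- run_experiment(pop, calibrated_abm_model(pop), abm_config())
traj
#> <trust_trajectory> strategy = baseline | 100 trials x 14 days
#>   delay rate: 10.6% (day 1) -> 9.3% (day 14)
#>   mean trust: 2.14 (day 1) -> 1.56 (day 14)
autoplot(traj)
```

The baseline feedback loop erodes both delay and trust: delayed care lowers
usage and trust, which lowers the next day's delay probability, while the
high-risk stratum (baseline delay risk > 0.20) starts with the highest trust
and loses it fastest.

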