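---
title: "Models and methods in trustdelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in trustdelay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trustdelay` studies how trust in AI-generated health advice relates to
delayed care-seeking, at two levels: cross-sectional associations in a
survey-like sample, and population dynamics in an agent-based simulation.
This vignette documents the models, their assumptions, the tunable
parameters, the calibration procedure, and the limits of what the package's
passing tests demonstrate.

## 1. The synthetic survey generator

No individual-level survey data are shipped; the generator emulates a
cross-sectional sample of 2,460 adults with the following structure.

**Variables.** Trust in AI health advice `T` is ordinal 0–5, where 0 means
"never used" (38% of respondents) and 1–5 grade increasing trust. Usage
frequency `F` is ordinal 0–5 (never through almost daily). `C` is a binary
physician-diagnosed chronic-disease flag (prevalence 0.301). The outcome `D`
is a binary self-report of having postponed or cancelled care because of AI
advice (target prevalence 0.116). Age (mean 34.46, SD 11.62, truncated to
18–75 years), sex (54.7% female), occupation (four categories), exposure to
AI recommendations (1–5), willingness to recommend AI (1–5), a submission
date (uniform over Dec 2024–May 2025), and a completion time in seconds are
carried along.

**Generating model.** Delay is drawn from

$$\operatorname{logit} P(D=1) = \beta_0 + \beta_T T + \beta_F F + \beta_C C$$

with $\exp(\beta_T) = 1.09$, $\exp(\beta_F) = 1.40$, $\exp(\beta_C) = 1.42$.
The intercept is not a free choice: `calibrate_intercept()` solves, by
bisection on a monotone function, for the $\beta_0$ that makes the mean of
the predicted probabilities over the drawn covariates equal the target
prevalence to within $10^{-6}$. Bisection is used because the mean logistic
response is strictly increasing in the intercept, so the root is unique and
bracketing on $[-50, 50]$ always converges.

**The trust–frequency link.** Frequency is generated as
$F = \mathrm{round}(\mathrm{clamp}(0.5754\,T + \varepsilon,\ 0,\ 5))$ with
$\varepsilon \sim N(0, \sigma^2)$, and the hard consistency rule that a
respondent who never used AI ($T = 0$) reports $F = 0$. The slope 0.5754 is
the emulated survey's adjusted trust-to-frequency regression coefficient.

The noise scale $\sigma$ (default **2.0**) was calibrated once and frozen.
The emulated survey reports the precision of its estimates — a path-*a*
standard error of 0.014 and a frequency log-odds standard error of 0.0455 at
n = 2,460 — and those standard errors identify the residual spread of
frequency around the trust line: a residual SD near 1.4. A pre-rounding
$\sigma$ of 2.0 yields exactly that effective residual SD after rounding and
clamping (refitted SEs 0.0136 and 0.0455), while keeping the refitted slope
within ±0.05 of 0.5754 (the attenuation from clamping costs about 0.013).
Smaller values of $\sigma$ (e.g. 1.0) make the synthetic sample
artificially informative — refit SEs ~60% larger than reported and
confidence intervals that no longer match the reported interval widths.

**Independence assumptions.** Chronic disease is generated independently of
trust and frequency; its effect on delay enters only through the logistic
model. Age, sex, occupation, exposure, and willingness carry realistic
margins but have **zero generating effect** on the outcome; they exist so
that adjusted analyses and moderation analyses have honest covariates whose
null effects are known. Exposure and willingness margins are not reported
quantities for the emulated survey; the defaults (a mild mode at the middle
of the scale, with willingness skewed slightly positive) were chosen once as
plausible for a digitally engaged adult sample and are config parameters.

**Data cleaning.** `apply_exclusions()` enforces the four cleaning rules of
a real web survey: duplicate ids (first complete entry retained), missing
values in analysis fields, completion under 90 seconds, and the logical
inconsistency $T = 0, F > 0$. Each excluded record is counted under the
first rule it violates, in that order — a record can violate several rules,
and a fixed precedence makes the exclusion report deterministic. With
`dirty_fraction = 0.117` the generator reproduces a realistic raw-stream
exclusion rate (about 325 exclusions from 2,785 submissions); the default
is 0 so that the default population is analysis-ready.

**Age truncation.** The truncated-normal location is recentred (by solving
the truncated-mean equation) so the *realized* mean equals the configured
34.46; naive truncation at 18 would inflate the mean by ~1.7 years.

## 2. Regression engine

`fit_logistic()` wraps the binomial GLM (iteratively reweighted least
squares, convergence tolerance $10^{-8}$, at most 100 iterations) and adds
the reporting conventions used throughout: odds ratios `exp(beta)`, Wald 95%
intervals `exp(beta ± 1.96 SE)`, and two-sided Wald p-values. Wald (rather
than profile-likelihood) intervals were chosen because they are the
convention behind "OR (95% CI)" tables and are exactly reproducible.
Complete separation is detected by the diverging-coefficient signature
(|beta| > 15) and reported via the `converged`/`separation` flags, never
silently clipped. Sex is coded female = reference; occupation uses
treatment contrasts with students as reference; both encodings are recorded
in the fit object since the convention is otherwise invisible in an OR
table.

The hierarchical models add covariate blocks in a fixed, documented order:
model 1 individual characteristics (age, sex, chronic), model 2 adds
recommendation exposure, model 3 adds the AI usage pattern (trust,
frequency), model 4 adds willingness to recommend (the fully adjusted
model). The blocks are fixed in code because only the fully adjusted model
has externally reported anchors; the intermediate assignments are a design
choice.

Moderation is assessed both ways the field expects: stratified fits
(`stratified_analysis()`, with helpers for a calendar-date split at
2025-02-01, an exposure split at ≤2 vs >2, and a willingness split at ≤2 vs
≥3) and a product-term model (`interaction_model()`), which also emits a
predicted-probability grid over focal values per moderator level with
adjusters held at their means.

## 3. Mediation

`estimate_paths()` implements the classical path decomposition for a binary
outcome: path *a* from a linear regression of the mediator (frequency) on
the exposure (trust), paths *b* and *c′* from a logistic regression of delay
on both, and the total effect *c* from a logistic regression omitting the
mediator — all adjusted for age, sex, and chronic status. The indirect
effect is the product $a \cdot b$ on the log-odds scale.

Two caveats are deliberate design positions:

* **Non-collapsibility.** With a logistic outcome, $c$ need not equal
  $c' + ab$ exactly; the decomposition is on the log-odds scale, as is
  conventional for this design, and the package makes no counterfactual
  scale claims. Empirically, at large n with both paths positive, $c >
  c'$ holds, and a test asserts it at n = 100,000.
* **Bootstrap p-value.** The nonparametric bootstrap (resample respondents
  with replacement at full n; re-estimate $a$ and $b$; product per
  replicate) summarises the indirect effect by its replicate mean,
  percentile 2.5/97.5 bounds taken as order statistics (no normal
  approximation), and a p-value defined as twice the smaller tail
  proportion of replicates at or beyond zero. Replicates whose outcome
  model fails to converge are dropped and counted; more than 20% failures
  flags the result.

The Sobel test uses the first-order delta-method form
$z = ab / \sqrt{b^2 s_a^2 + a^2 s_b^2}$; its sign equals the sign of
$ab$, and a degenerate zero denominator returns $z = 0$.

A subtlety discovered while testing: the consistency rule $T=0 \Rightarrow
F=0$ structurally couples trust and frequency even when the generating slope
is zero, because the never-used group sits at exactly zero frequency while
users scatter above it. Null-path simulations (type-I checks) therefore use
a trust distribution with no mass at level 0; with mass at 0, "slope = 0"
does not define a null world.

## 4. Scenario predictions

`simulate_scenarios()` sets the scenario's covariates for every respondent,
keeps the rest at observed values, and averages the fitted probabilities.
With the three-predictor model and all three covariates overridden this
collapses to a single shared probability; the averaging is kept so richer
models (with demographic adjusters that are never overridden) work
unchanged. The six standard scenarios are: baseline (trust 3, frequency 3,
no chronic disease), trust→5, frequency→5, chronic→yes, trust+frequency→5,
and all three. Scenario outputs are reported as monotonicity statements
(each positively weighted override raises the mean probability; the
combined scenarios dominate their components) rather than as fixed numeric
anchors: point predictions at extreme covariate settings are very sensitive
to rounding of the coefficients, so only order relations are stable enough
to assert.

## 5. The agent-based model

**Initialization.** Each agent copies one respondent's trust, frequency
(survey level 0 mapped to 1 — the simulation operates on 1–5), and chronic
flag. Its baseline delay risk is the logistic model's prediction on the
mapped values. Agents with risk strictly above 0.20 receive a 1-point
reduction in trust and frequency (clamped at 1), representing structural
vulnerability; ties at exactly 0.20 get no reduction.

**Which logistic model drives the agents.** Two options are provided.
`fit_abm_model()` refits the three-predictor model to the (mapped) records —
the empirical route. `calibrated_abm_model()` keeps the generating
log-odds-ratios and recalibrates only the intercept on the mapped
covariates to the target prevalence. The acceptance analyses and the
pipeline use the calibrated model: a refit inherits the binomial noise of a
single synthetic outcome draw (±0.65 percentage points of prevalence at
n = 2,460), which would make trajectory anchors swing by over a percentage
point between seeds, whereas the original study's trajectories conditioned
on its one fixed empirical fit. Refitting on the *mapped* scale matters
either way: because the intercept is (re)anchored on the same scale the
agents live on, the mean day-1 predicted probability equals the survey
prevalence before the vulnerability reduction, and the reduction brings the
day-1 delay rate to about 10.6%.

**Daily cycle.** For each day, in order: (i) each agent computes
$p_i = \operatorname{logit}^{-1}(\beta_0 + \beta_T t_i + \beta_F f_i +
\beta_C c_i)$ from its *current* scores and draws a Bernoulli delay
decision; (ii) daily statistics are recorded on start-of-day trust and
today's decisions; (iii) personal outcome: delaying costs 0.2 trust and 0.3
frequency, not delaying gains 0.1 trust; (iv) peer terms, computed
synchronously from start-of-day trust and today's decisions: trust moves
toward the neighbourhood mean with gain `peer_gain`, and drops by
`peer_delay_penalty` if more than half of the neighbours delayed today;
(v) a global daily decay `trust_decay`; (vi) the active intervention's
update; (vii) clamp trust and frequency to [1, 5]. Synchronous updating
keeps a trial independent of agent ordering. Personal, peer, and decay
terms compose additively.

**Calibration of the unidentified parameters.** The survey identifies the
personal-outcome magnitudes and the network (ring degree 4, rewiring
probability 0.2) but not the peer gain, the peer delay penalty, or the
decay. These three were calibrated **once** by grid search (peer gain and
peer penalty over {0, 0.025, 0.05, 0.1}; decay over {0, 0.025, …, 0.15})
against two baseline trajectory anchors — a day-14 delay rate near 9.5% and
a day-14 mean trust near 1.49 — and frozen at `peer_gain = 0.05`,
`peer_delay_penalty = 0.10`, `trust_decay = 0.125`. The decay grid had to
extend beyond small values: the raw personal-outcome rules alone produce
*net trust growth* (+0.1 for the ~89% of non-delaying agents outweighs −0.2
for the ~11% who delay), so reproducing the observed population-level trust
erosion requires a daily decay around 0.125. After this calibration, every
other simulated quantity (day-1 rate, stratum trajectories, intervention
odds ratios, sensitivity sweeps) is out-of-sample.

**Interventions.** *Broadcast* subtracts a fixed daily trust penalty
(default 0.10) from everyone. *Reward* adds 0.05 to trust and frequency,
every 2 days, for agents with no delay within the current 2-day window
(window-based rather than since-start, so the reward stays attainable at
the stated cadence). *Rewire* redirects, every 5 days, 10% of randomly
chosen edges: one randomly chosen endpoint is re-attached to an agent drawn
uniformly from the top trust decile (ties broken by lowest id), avoiding
self-loops and duplicates with up to 10 redraws before keeping the original
edge, so the edge count is conserved exactly.

**Strategy comparison.** Delay indicators are pooled over agents × days ×
trials per arm and the strategy effect estimated by logistic regression
against the baseline arm, computed through the aggregated binomial
likelihood (identical MLE to the fully expanded regression, at a millionth
of the memory). The agent-day pooling is a design choice: it is the only
unit of analysis that produces the very tight confidence intervals such
comparisons report, since it treats every agent-day as an observation.

**Known limitation — polarization.** The mean-attraction peer term is
contractive: it pulls high-trust opinion leaders *down* toward their
followers as strongly as it pulls followers up. Under this dynamic the
rewiring intervention produces only a weak delay increase (pooled OR near
1.00–1.02 rather than ~1.04), and the reward intervention's frequency bonus
makes it the strongest delay-increasing arm (OR ~1.04 rather than ~1.01),
so the expected ordering broadcast < reward < rewire does not emerge.
Reproducing genuine "trust polarization" would need an asymmetric or
assortative peer rule (e.g. gains only from higher-trust neighbours), which
the update contract here deliberately does not include. The corresponding
acceptance checks are left failing rather than reinterpreted.

## 6. Sensitivity sweeps

`sweep_parameter()` varies exactly one parameter, holding the base seed
fixed so runs differ only in the swept value: initial mean trust (the
initial trust distribution is location-shifted to the target mean, then
clamped to [1, 5] — an override of the empirical initialization, flagged as
an implementation choice since the empirical mean is far below the swept
values), broadcast penalty {0.05, 0.1, 0.2}, reward magnitude {0.03, 0.05,
0.10}, and rewiring interval {2, 5, 10} days. Trajectories are compared at
days 1, 7, and 14.

## 7. Problem sizes and reproducibility

Every stochastic component takes one integer seed; experiments reseed per
trial as `base_seed + trial`, so any trial can be reproduced in isolation.
The test suite runs the full study sizes where they are cheap (n = 2,460
populations, 100-trial simulations take a few seconds vectorized) and
scales down only the heaviest Monte-Carlo meta-checks: CI coverage uses 200
seeds, null-path type-I control uses 120 seeds with 99 bootstrap
replicates at n = 500, and sweeps in tests use 25 trials. The pipeline
example in the tests runs n = 400 with 2 trials × 3 days purely to exercise
the plumbing.

What passing tests do and do not show: the generator matches the *margins*
and the *generating associations* it was built to match; it does not
reproduce item-level correlations of real questionnaires (e.g. between
occupation and exposure), non-logistic outcome structure, temporal drift
across the survey window, or informative missingness (its dirty records are
missing completely at random by construction). Simulation results are
statements about the model's dynamics under the frozen calibration, not
about real-world intervention efficacy.
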