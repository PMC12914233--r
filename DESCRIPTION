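Package: trustdelay
Title: Trust in AI Health Advice and Delayed Care-Seeking: Survey Synthesis, Mediation, and Agent-Based Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how trust in AI-generated health advice
    relates to delayed health care-seeking. Provides a calibrated synthetic
    survey generator (trust, usage frequency, chronic-disease status, and a
    binary delay outcome with a logistic generating model), logistic
    regression analyses (univariate screens, hierarchical models, stratified
    and interaction models), Baron-Kenny mediation with Sobel test and
    nonparametric bootstrap of the indirect effect, scenario-based predicted
    probabilities, and an agent-based simulator of trust-delay feedback on a
    Watts-Strogatz small-world network with broadcast, reward, and rewiring
    interventions plus one-way sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
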