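Package: copdcea
Title: Hybrid Decision-Tree and Markov Cost-Effectiveness Model for COPD Maintenance Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hybrid decision-tree/Markov cohort cost-effectiveness
    model for inhaled maintenance therapy in chronic obstructive pulmonary
    disease (COPD). A one-year within-trial decision tree accrues costs,
    life-years and quality-adjusted life-years directly from 52-week trial
    outputs; a lifetime six-state Markov model (three FEV1-defined severity
    grades stratified by recent exacerbation history, plus death) extrapolates
    outcomes to a 35-year horizon. Produces discounted per-arm results, cost
    categories, incremental cost-effectiveness ratios with dominance handling,
    one-way (tornado) sensitivity analyses, declarative scenario analyses,
    and probabilistic sensitivity analysis with Cholesky-correlated draws and
    cost-effectiveness acceptability curves. Includes a synthetic-data
    generator emitting complete, internally consistent parameter bundles and
    life tables so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
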