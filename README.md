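# copdcea

A cost-effectiveness model for inhaled maintenance therapy in chronic
obstructive pulmonary disease (COPD), written for health economists and
health-technology-assessment (HTA) analysts who need a transparent, tested,
scriptable implementation of the standard UK reference-case analysis:
lifetime horizon, annual cycles, 3.5%/year discounting of costs and
benefits, and a willingness-to-pay decision rule on quality-adjusted
life-years (QALYs).

## The model

The model is a hybrid of two parts:

1. **A within-trial decision tree (year 1).** Costs, life-years (LYs) and
   QALYs are accrued directly from 52-week trial outputs per treatment arm:
   moderate and severe exacerbation rates (events/patient-year), annual
   pneumonia probability, within-trial mortality, treatment
   discontinuation (costed as 26 weeks of assigned therapy followed by 26
   weeks of class-mix-weighted replacement therapy), and an EQ-5D utility
   trajectory integrated by the trapezoid rule.

2. **A Markov cohort model (years 2 onward, default horizon 35 years).**
   Six living states — three FEV₁-defined severity grades (moderate:
   50–<80% predicted; severe: 30–<50%; very severe: <30%), each split by
   recent exacerbation history (an exacerbation within the previous annual
   cycle) — plus absorbing death. Within each cycle the order of events is
   death → severity progression (worsening only) → exacerbation
   expectation from origin-state risks → history-stratum update. State
   death probability applies a severity relative risk on the log-survival
   scale, `q_state = 1 − (1 − q_background)^RR`, to a background life table
   with COPD deaths removed. Decedents accrue half a cycle of LY, QALY and
   continuous costs.

Per-arm discounted totals combine into pairwise comparisons:

- ICER = ΔC/ΔE, reported per QALY and per LY, with *dominant* (more
  effective, cheaper) and *dominated* (less effective, costlier) verdicts
  in place of negative ratios;
- one-way sensitivity analysis (±20% perturbations, tornado ordering);
- declarative scenario analyses (discount rates, horizon, discontinuation,
  post-trial direct treatment effect with optional linear waning, societal
  perspective, pooled replacement mix, state-utility year-1 valuation);
- probabilistic sensitivity analysis: beta/gamma/log-normal marginals,
  a Cholesky-factored correlated block for the transition and
  exacerbation probabilities, net-monetary-benefit cost-effectiveness
  acceptability curves (CEAC), `P(λ·ΔQ − ΔC > 0)`.

A synthetic-data module generates complete, internally consistent
parameter bundles (severity gradients, arm effect sizes, Gompertz life
tables), so every stage of the pipeline is testable with no external data.

The bundled base-case configuration (`cea_base_config()`) carries
published UK-2018 point estimates for costs, utilities, event
disutilities, mortality relative risks and drug prices, together with
clearly-labelled synthetic stand-ins for quantities that are only
available in unpublished supplementary material (trial outputs, transition
probabilities, class mixes, life table). Results computed from it are
therefore internally consistent but are not a reproduction of any
published analysis.

## Worked example

```r
library(copdcea)

params <- load_parameters(cea_base_config())
result <- run_cea(params, intervention = "FF_UMEC_VI")
result
#> <cea_result> 3 arms, 2 comparisons
#>   FF_UMEC_VI vs FF_VI: dCost 1534, dQALY 0.1344, ICER/QALY 11411
#>   FF_UMEC_VI vs UMEC_VI: dCost 829, dQALY 0.1124, ICER/QALY 7374
```

Triple therapy (FF/UMEC/VI) costs £1534 more than FF/VI over a lifetime
per patient (discounted, GBP 2018) and yields 0.134 extra QALYs, an ICER
of £11 411 per QALY gained — cost-effective at the conventional £20 000
per QALY threshold. The standard results layout:

```r
library(dplyr)
cea_table(result) |>
  filter(quantity %in% c("any_exacerbation", "lys_discounted",
                         "qalys_discounted", "total_cost"))
#> # A tibble: 4 × 6
#>   quantity         FF_UMEC_VI    FF_VI  UMEC_VI FF_UMEC_VI_vs_FF_VI FF_UMEC_VI_vs_UMEC_VI
#>   <chr>                 <dbl>    <dbl>    <dbl>               <dbl>                 <dbl>
#> 1 any_exacerbation       8.20     8.32     8.44              -0.117                -0.239
#> 2 lys_discounted         8.83     8.70     8.70               0.128                 0.122
#> 3 qalys_discounted       6.40     6.26     6.29               0.134                 0.112
#> 4 total_cost         25225.   23691.   24396.              1534.                  829.
```

Sensitivity and scenario layers chain off the same bundle:

```r
tornado <- run_owsa(params, intervention = "FF_UMEC_VI", comparator = "FF_VI")
autoplot(tornado)

scenarios <- run_scenario_suite(params, intervention = "FF_UMEC_VI")

psa <- run_psa(params, psa_spec(params, n_draws = 1000, seed = 42),
               intervention = "FF_UMEC_VI")
glance(psa)       # mean deltas + P(cost-effective at £20 000/QALY)
plot_ceac(psa)
```

A command-line wrapper covers the same pipeline
(`system.file("cli", "copdcea", package = "copdcea")`): subcommands
`run-base`, `owsa`, `psa`, `scenarios` and `generate`, each writing
numeric CSV outputs plus a JSON run manifest.

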