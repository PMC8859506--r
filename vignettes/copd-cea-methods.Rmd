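---
title: "Methods: a hybrid decision-tree/Markov cost-effectiveness model for COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid decision-tree/Markov cost-effectiveness model for COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdcea)
```

## The decision problem

The package compares inhaled maintenance therapies for symptomatic COPD
with an exacerbation history, from a health-service perspective with an
optional societal extension. The comparison of interest is single-inhaler
triple therapy (ICS/LAMA/LABA) against each of two dual therapies
(ICS/LABA and LAMA/LABA). Because trial follow-up (52 weeks) is far
shorter than the decision horizon, the model is a hybrid: a within-trial
decision tree uses the trial outputs directly for year 1, and a Markov
cohort model extrapolates from the trial-end state distribution to a
lifetime (35-year) horizon.

## States and dynamics

Six living states — severity grades *moderate* (FEV₁ 50–<80% predicted),
*severe* (30–<50%) and *very severe* (<30%), each stratified by whether an
exacerbation occurred in the previous annual cycle — plus absorbing death.
COPD is treated as progressive: no transition toward a milder grade
carries probability mass, and the loader rejects configurations that try.

Within each annual cycle the engine applies, in order:

1. **Death.** Background annual probability `q` (life-table lookup at
   `floor(age)`) scaled by a severity relative risk on the log-survival
   scale: `1 − (1 − q)^RR`. This treats the RR as a hazard multiplier,
   which keeps the result a probability for any `RR ≥ 0`.
2. **Severity progression** among survivors, worsening only, with
   time-homogeneous origin-state probabilities (age enters only through
   background mortality). A direct moderate→very-severe probability is
   supported and defaults to 0.
3. **Exacerbation expectation** from origin-state risks applied to
   survivors. Annual probabilities of ≥1 moderate and ≥1 severe
   exacerbation are treated as expected counts per person-year (a cohort
   expectation, not a sample); the probability of *any* exacerbation used
   for the history stratum is `1 − (1 − p_mod)(1 − p_sev)`, i.e. the two
   event types are combined as if independent.
4. **Stratum update.** A fraction `p_any` of each origin state's survivors
   enters the recent-exacerbation stratum of its (possibly progressed)
   severity; the rest enters the no-recent stratum.

Deaths are applied first so that events are never credited to decedents
twice; decedents accrue half a cycle of life-years, QALYs and continuous
costs (maintenance, drug, replacement) — the person-time convention,
which approximates a half-cycle correction while keeping event
expectations simple. Occupancy is conserved to 1e-9 per cycle and tested.

Pneumonia is the only adverse event: its annual probability depends on
the arm only (not on severity), it costs and disutilizes but confers no
mortality or state change, the excess COPD mortality rates being taken to
absorb it.

## The within-trial year

Expected event counts are rates × person-time, where survivors contribute
1 year and within-trial decedents 0.5 year. Drug costs follow the
discontinuation rule: discontinuers receive 26 weeks of assigned therapy
then 26 weeks of replacement therapy (26 weeks = 26·7/30 thirty-day
units), priced as the class-mix-weighted mean of the four replacement
classes; continuing patients receive `cost_per_30d × 365.25/30`.
Discontinuation status is fixed at trial end — discontinued patients stay
on replacement therapy for the rest of the horizon. Maintenance cost in
year 1 is weighted by the trial-end severity mix, the only per-arm
severity datum available within the year. Utilities come from the pooled
baseline EQ-5D plus per-arm change-from-baseline at visit weeks,
integrated by the trapezoid rule with flat extension outside the visited
range; event disutilities are subtracted as one-off QALY losses.

## Discounting and comparison

The trial year is discount period 0 (undiscounted, the usual convention
for first-year costs and outcomes); Markov cycle *k* is discounted by
`(1+r)^{-k}` at 3.5%/year for both costs and benefits by default.
Expected exacerbation counts are reported undiscounted and include the
trial year. ICERs are computed from unrounded internal deltas; *dominant*
/ *dominated* verdicts replace negative ratios, and a zero effect
difference is labelled an undefined ratio rather than ±∞.

## Key parameters

| Parameter | Default | Units / notes |
|---|---|---|
| Horizon | 35 years | annual cycles, fixed at 1 year |
| Discount rates | 0.035/yr each | costs and benefits separately settable |
| Start age | 65.3 years | life-table lookup at `floor(age)` |
| Mortality RR | 1.89 / 3.63 / 8.33 | by severity, ≥1 and non-decreasing |
| State utilities | 0.787 / 0.750 / 0.647 | strictly decreasing with severity |
| Event QALY loss | 0.011 / 0.020 / 0.011 | moderate exac / severe exac / pneumonia |
| Maintenance cost | 216.82 / 798.95 / 2297.98 | GBP-2018 per annum, strictly increasing |
| Event costs | 568.48 / 6120.30 / 1087.98 | GBP-2018 per event |
| Drug cost / 30 d | 44.50 / 22.00 / 32.50 | triple / ICS-LABA / LAMA-LABA |
| Replacement classes / 30 d | 29.29 / 31.79 / 32.50 / 61.08 | LAMA, ICS/LABA, LAMA/LABA, ICS/LAMA/LABA |
| WTP grid | £0–50 000 by £1000 | £20 000 always included |
| PSA draws | 10 000 | master seed + per-draw substreams |

The pneumonia event cost is the ambulatory/inpatient mix weighted by the
hospitalised fraction (55%); the bundled configuration stores a synthetic
decomposition consistent with the published weighted cost.

## Sensitivity analyses

**One-way (tornado).** Each parameter of the default set (moderate and
very-severe utilities, all exacerbation risks jointly, mortality RRs,
per-arm drug costs, maintenance costs) is perturbed ±20% holding all else
fixed, the full model re-run, and rows sorted by ICER span. Perturbations
that would breach an invariant (e.g. a utility overtaking the next-milder
grade) are clamped to the feasible boundary with a warning rather than
rejected, so the tornado always has both bounds.

**Probabilistic.** Marginals follow standard HTA practice: beta for
probabilities and utilities (method-of-moments from published 95% CIs
where available, otherwise an effective per-arm sample size of 4000,
typical of a large phase-III arm), gamma for costs (CV 0.2), log-normal
for mortality RRs (CV 0.2), gamma for trial exacerbation rates (CV 0.1),
and Dirichlet (effective n 4000) for trial-end state distributions. Drug
prices are list prices and are not sampled. The transition and per-state
exacerbation probabilities form a correlated block on the logit scale
(marginal sd 0.1, exchangeable correlation 0.3) reflecting their joint
estimation by the underlying risk equations; the block covariance is
factored by the package's own Cholesky routine (semi-definite inputs
handled by zero pivots, negative leading minors rejected by order). Each
draw uses a substream seed derived deterministically from the master seed
and draw index, so the PSA is reproducible and order-independent. A draw
violating a structural ordering (risk monotonicity, utility ordering) is
rejected and redrawn, up to 100 attempts; with the default spreads
rejections are rare, and the cap turns a mis-specified spec into an error
rather than a silent bias.

CEACs apply the net-monetary-benefit rule: at each willingness-to-pay λ,
the curve is the fraction of draws with `λ·ΔQALY − ΔC > 0`.

## Scenarios

The scenario engine shallow-merges named overrides onto the base bundle
and re-runs the pipeline; application is idempotent and the empty
scenario reproduces the base case bit-for-bit. The packaged suite covers
0% and 5% discounting, excluded within-trial mortality, a direct
post-trial exacerbation effect for 1/3/5 years (constant or waning
linearly to zero, with the reduction taken from the within-trial combined
exacerbation rate ratio against the comparator at hand), no
discontinuation, a trial-follow-up horizon (zero Markov cycles), pooled
replacement mixes (unweighted mean across arms), the societal
perspective, and year-1 valuation by state utilities instead of the
EQ-5D trajectory. Societal costs use a human-capital interpretation — a
user-supplied cost per event and per severity-year — since no published
values exist; they default to round placeholder values in the synthetic
generator and affect only the societal scenario.

## Synthetic data

`generate_parameters()` emits full bundles with the statistical structure
the model assumes: exacerbation risk increasing with severity
(ratio 1.25/grade) and with recent history (ratio 1.35), utilities
decreasing and costs increasing with severity, a Gompertz life table
(`q(a) = 1 − exp(−q40·e^{rate·(a−40)})`, closed at age 110), and arm
effects in the directions a triple-vs-dual trial reports (lower
exacerbation rates, milder trial-end distribution, higher pneumonia risk
in ICS-containing arms). Where a published point estimate exists it is
the default; remaining magnitudes were chosen once as clinically
plausible for a severe-COPD cohort. The generator does **not** attempt to
match any patient-level data, and passing tests on generated bundles
demonstrate internal correctness of the accounting — conservation,
monotonicity, planted-effect recovery — not agreement with any real
population. The bundled base-case configuration is the same idea frozen
to a file: published point estimates plus synthetic stand-ins, with
provenance flagged in `meta`, and model outputs from it should be read as
internally consistent illustrations rather than reproductions of a
published analysis.

## Numerical choices

- Occupancy conservation tolerance 1e-9; validation errors name the field
  and bound.
- Life-table lookup clamps ages outside [40, 110] to the table edge; the
  terminal row closes the table at `q = 1`.
- `write_parameters()` marks its life table as already COPD-adjusted so a
  round trip does not re-warn or double-adjust.
- Cholesky: pivots below a relative tolerance of 1e-10 are treated as
  zero (semi-definite case); a negative pivot aborts with the offending
  leading-minor order.
- OWSA clamping keeps strict orderings by an ε of 1e-9.
- Ties in tornado spans are broken alphabetically by parameter id, so
  output order is independent of spec order.

## Problem sizes

The test suite exercises the engine at horizons of 3–26 years, PSAs of
25–400 draws, and 100 000-draw checks of the correlated-sampling
covariance; the acceptance script runs the full base case, the scenario
suite, the tornado, and a 10 000-draw PSA (a few minutes on one core).
These sizes were chosen to give stable Monte Carlo comparisons at the
3-standard-error level used in the tests.

## Limitations

- Cohort expectations only: no individual-level microsimulation, no
  tunnel states beyond the single-cycle exacerbation-history stratum.
- Pairwise comparisons only; no frontier across three-plus strategies and
  no expected value of perfect information.
- The exacerbation "rates" in the Markov phase are annual probabilities
  of ≥1 event used as expected counts, which undercounts multiple events
  per year relative to a true rate model.
- Whether the within-trial year's event expectations should be reduced
  for decedents' lost person-time is a convention (0.5 year here), and
  the death-cycle life-year credit likewise; both are flagged in this
  vignette rather than hidden in code.
- Sex-specific life tables are not modelled; the bundle carries a single
  unisex table (the male fraction is recorded in settings for users who
  supply sex-specific inputs externally).
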