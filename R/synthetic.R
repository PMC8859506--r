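#' Specification for the synthetic parameter generator
#'
#' Controls the statistical structure of generated bundles: severity
#' gradients (costs increasing, utilities decreasing, exacerbation risk
#' increasing with severity and with recent-exacerbation history),
#' between-arm effect sizes (the triple-therapy arm has lower exacerbation
#' rates and a trial-end distribution shifted toward milder states;
#' ICS-containing arms have higher pneumonia risk), and a two-parameter
#' exponential-increase-with-age (Gompertz) background life table.
#'
#' Numeric defaults are the published UK-2018 point estimates where those
#' exist (state costs and utilities, event costs and disutilities,
#' mortality relative risks, 30-day drug and replacement-class prices);
#' the remaining quantities (annual transition/exacerbation probabilities,
#' per-arm 52-week outputs, life-table shape) default to values chosen once
#' as clinically plausible for a severe-COPD trial cohort and are synthetic.
#'
#' @param seed Integer seed; generation is deterministic in it.
#' @param exac_rate_ratio Combined exacerbation-rate ratios of the two dual
#'   arms relative to the triple arm (named `FF_VI`, `UMEC_VI`).
#' @param pneumonia_ratio Pneumonia-probability ratios relative to the
#'   triple arm (ICS arms elevated).
#' @param distribution_shift Fraction of trial-end moderate-state occupancy
#'   moved one grade worse in each dual arm.
#' @param severity_exac_gradient Multiplicative increase in exacerbation
#'   probability per severity grade.
#' @param history_exac_gradient Multiplicative increase in the
#'   recent-exacerbation stratum over the no-recent stratum.
#' @param progression Annual severity-progression probabilities
#'   (`moderate_to_severe`, `severe_to_very_severe`,
#'   `moderate_to_very_severe`).
#' @param life_shape Gompertz life-table shape, see [generate_life_table()].
#' @param noise_sd Relative jitter applied to the synthetic (non-published)
#'   quantities; 0 gives the deterministic skeleton.
#' @return A list of class `"cea_generator_spec"`.
#' @export
generator_spec <- function(seed = 1,
                           exac_rate_ratio = c(FF_VI = 1.18, UMEC_VI = 1.33),
                           pneumonia_ratio = c(FF_VI = 0.88, UMEC_VI = 0.63),
                           distribution_shift = c(FF_VI = 0.05, UMEC_VI = 0.03),
                           severity_exac_gradient = 1.25,
                           history_exac_gradient = 1.35,
                           progression = c(moderate_to_severe = 0.07,
                                           severe_to_very_severe = 0.10,
                                           moderate_to_very_severe = 0),
                           life_shape = c(q40 = 0.0012, rate = 0.088),
                           noise_sd = 0) {
  structure(as.list(environment()), class = "cea_generator_spec")
}

#' Generate a background life table with Gompertz-increasing mortality
#'
#' Annual death probability `q(a) = 1 - exp(-q40 * exp(rate * (a - 40)))`
#' for integer ages 40--110, with `q(110)` forced to 1 (closing the
#' table). Emulates the shape of a general-population life table.
#'
#' @param shape Named vector: `q40` (hazard at age 40) and `rate`
#'   (log-hazard slope per year of age).
#' @param ages Integer ages covered.
#' @return A tibble with columns `age` and `q`, strictly increasing in `q`.
#' @export
generate_life_table <- function(shape = c(q40 = 0.0012, rate = 0.088),
                                ages = 40:110) {
  check_range(shape[["q40"]], "shape$q40", lower = 1e-12)
  check_range(shape[["rate"]], "shape$rate", lower = 1e-12)
  q <- 1 - exp(-shape[["q40"]] * exp(shape[["rate"]] * (ages - 40)))
  q <- pmin(q, 1)
  q[ages == max(ages)] <- 1
  tibble::tibble(age = as.integer(ages), q = q)
}

#' Generate a complete, internally consistent parameter bundle
#'
#' Produces a full `"cea_parameters"` bundle (three treatment arms) with
#' the statistical structure the model assumes; the result always passes
#' [validate_parameters()]. Deterministic in `spec$seed`. With all effect
#' sizes at 1 (and shifts at 0) the three arms are identical.
#'
#' @param spec A `"cea_generator_spec"`.
#' @return A `"cea_parameters"` bundle.
#' @export
generate_parameters <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "cea_generator_spec"))
  with_seed(as.integer(spec$seed), generate_parameters_impl(spec))
}

generate_parameters_impl <- function(spec) {
  jitter1 <- function(x) {
    if (spec$noise_sd <= 0) x else x * exp(stats::rnorm(length(x), 0, spec$noise_sd))
  }

  # exacerbation risk: increases with severity and with recent history
  g_sev <- spec$severity_exac_gradient^(0:2)
  p_mod_base <- pmin(0.95, jitter1(0.40 * g_sev))
  p_sev_base <- pmin(0.95, jitter1(0.10 * g_sev))
  exacerbation <- tibble::tibble(
    severity = rep(cea_severities(), each = 2),
    stratum = rep(c("no_recent", "recent"), 3),
    p_moderate = pmin(0.97, as.vector(rbind(p_mod_base,
                                            p_mod_base * spec$history_exac_gradient))),
    p_severe = pmin(0.97, as.vector(rbind(p_sev_base,
                                          p_sev_base * spec$history_exac_gradient)))
  )
  # cap must preserve monotonicity: enforce explicitly after jitter
  for (col in c("p_moderate", "p_severe")) {
    m <- matrix(exacerbation[[col]], nrow = 2)     # rows: no_recent, recent
    m[2, ] <- pmax(m[2, ], m[1, ])
    m[1, ] <- cummax(m[1, ]); m[2, ] <- cummax(m[2, ])
    exacerbation[[col]] <- as.vector(m)
  }

  transitions <- tibble::tibble(
    severity = cea_severities(),
    p_to_severe = c(jitter1(spec$progression[["moderate_to_severe"]]), 0, 0),
    p_to_very_severe = c(spec$progression[["moderate_to_very_severe"]],
                         jitter1(spec$progression[["severe_to_very_severe"]]), 0)
  )

  # published UK-2018 point estimates
  costs <- list(
    maintenance = c(moderate = 216.82, severe = 798.95, very_severe = 2297.98),
    moderate_exac = 568.48,
    severe_exac = 6120.30,
    pneumonia = 1087.98,
    replacement_class = c(lama = 29.29, ics_laba = 31.79,
                          lama_laba = 32.50, ics_lama_laba = 61.08),
    societal = list(per_moderate_exac = 120, per_severe_exac = 850,
                    per_pneumonia = 300,
                    per_severity_year = list(moderate = 150, severe = 400,
                                             very_severe = 900))
  )
  utilities <- list(
    state = c(moderate = 0.787, severe = 0.750, very_severe = 0.647),
    state_ci = tibble::tibble(severity = cea_severities(),
                              lower = c(0.771, 0.731, 0.598),
                              upper = c(0.802, 0.786, 0.695)),
    disutility = c(moderate_exac = 0.011, severe_exac = 0.020,
                   pneumonia = 0.011),
    disutility_ci = tibble::tibble(
      event = c("moderate_exac", "severe_exac", "pneumonia"),
      lower = c(0.006, 0.020, 0.006),
      upper = c(0.020, 0.030, 0.020)),
    trial_baseline = 0.72,
    trial_trajectory = NULL
  )
  mortality <- list(
    life_table = generate_life_table(spec$life_shape),
    rr = c(moderate = 1.89, severe = 3.63, very_severe = 8.33)
  )

  # arms: triple-therapy reference, dual arms scaled by the effect sizes
  drug_costs <- c(FF_UMEC_VI = 44.50, FF_VI = 22.00, UMEC_VI = 32.50)
  base_rate_mod <- 0.78
  base_rate_sev <- 0.13
  base_pneu <- 0.08
  base_death <- 0.015
  base_disc <- c(FF_UMEC_VI = 0.18, FF_VI = 0.22, UMEC_VI = 0.20)
  mixes <- list(
    FF_UMEC_VI = c(lama = 0.10, ics_laba = 0.18, lama_laba = 0.12,
                   ics_lama_laba = 0.60),
    FF_VI = c(lama = 0.08, ics_laba = 0.16, lama_laba = 0.12,
              ics_lama_laba = 0.64),
    UMEC_VI = c(lama = 0.10, ics_laba = 0.17, lama_laba = 0.11,
                ics_lama_laba = 0.62)
  )
  # trial-end severity mix of the reference arm; recent-exacerbation share
  # tied to the year-1 exacerbation probability
  sev_mix_ref <- c(moderate = 0.40, severe = 0.41, very_severe = 0.19)
  recent_share <- 0.55

  trial_end_for <- function(shift) {
    mix <- sev_mix_ref
    moved <- mix[["moderate"]] * shift
    mix[["moderate"]] <- mix[["moderate"]] - moved
    mix[["severe"]] <- mix[["severe"]] + moved * 0.7
    mix[["very_severe"]] <- mix[["very_severe"]] + moved * 0.3
    d <- as.vector(rbind(mix * (1 - recent_share), mix * recent_share))
    stats::setNames(d, cea_living_states())
  }

  ratio <- c(FF_UMEC_VI = 1, spec$exac_rate_ratio)
  pneu_ratio <- c(FF_UMEC_VI = 1, spec$pneumonia_ratio)
  shift <- c(FF_UMEC_VI = 0, spec$distribution_shift)
  arms <- purrr::imap(drug_costs, function(cost, label) {
    list(
      label = label,
      drug_cost_30d = cost,
      rate_moderate = base_rate_mod * ratio[[label]],
      rate_severe = base_rate_sev * ratio[[label]],
      p_pneumonia = min(0.97, base_pneu * pneu_ratio[[label]]),
      p_death = min(1, base_death * (1 + 0.15 * shift[[label]] / 0.05)),
      p_discontinuation = base_disc[[label]],
      replacement_mix = mixes[[label]],
      trial_end = trial_end_for(shift[[label]])
    )
  })

  bundle <- structure(
    list(transitions = transitions, exacerbation = exacerbation,
         mortality = mortality, costs = costs, utilities = utilities,
         arms = arms, settings = default_settings(),
         meta = list(provenance = "synthetic",
                     generator_seed = spec$seed)),
    class = "cea_parameters"
  )
  validate_parameters(bundle)
  bundle
}

#' Generate a PSA specification for a bundle
#'
#' Distribution means equal the bundle's point estimates; all spreads scale
#' with `noise_scale` (0 gives a degenerate spec). The correlated
#' transition/exacerbation block covariance is positive semi-definite by
#' construction and accepted by [cholesky_factor()].
#'
#' @param bundle A `"cea_parameters"` bundle.
#' @param noise_scale Global spread multiplier.
#' @param ... Passed to [psa_spec()].
#' @return A `"cea_psa_spec"`.
#' @export
generate_psa_spec <- function(bundle, noise_scale = 1, ...) {
  psa_spec(bundle, noise_scale = noise_scale, ...)
}
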