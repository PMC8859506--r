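SCENARIO_KEYS <- c(
  "discount_cost", "discount_benefit", "include_trial_mortality",
  "apply_discontinuation", "horizon_years", "posttrial_effect_years",
  "posttrial_effect_waning", "pooled_replacement_mix", "perspective",
  "trial_utility_source"
)

#' Define a named scenario
#'
#' A scenario is a shallow set of overrides on the base configuration.
#' Recognised keys: `discount_cost`, `discount_benefit` (fractions/yr),
#' `include_trial_mortality`, `apply_discontinuation` (logicals),
#' `horizon_years` (1 restricts the model to the trial follow-up, i.e.
#' zero Markov cycles), `posttrial_effect_years` (0/1/3/5) with
#' `posttrial_effect_waning` (`"none"`/`"linear"`),
#' `pooled_replacement_mix` (logical: average the replacement-class mix
#' across arms), `perspective` (`"health_service"`/`"societal"`), and
#' `trial_utility_source` (`"trial_eq5d"`/`"state_utilities"`).
#'
#' @param name Scenario label.
#' @param ... Overrides, `key = value`.
#' @return A list of class `"cea_scenario"`.
#' @export
scenario_spec <- function(name, ...) {
  overrides <- list(...)
  bad <- setdiff(names(overrides), SCENARIO_KEYS)
  if (length(bad)) {
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(SCENARIO_KEYS, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, overrides = overrides), class = "cea_scenario")
}

#' Apply a scenario to a parameter bundle
#'
#' Shallow-merges the scenario's overrides into the bundle settings (and,
#' for `pooled_replacement_mix`, the per-arm replacement mixes). Untouched
#' fields are identical to the base; application is idempotent.
#'
#' @param base A `"cea_parameters"` bundle.
#' @param scenario A `"cea_scenario"` (see [scenario_spec()]).
#' @return The modified, still-valid bundle.
#' @export
apply_scenario <- function(base, scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  ov <- scenario$overrides
  if (isTRUE(ov$pooled_replacement_mix)) {
    mixes <- do.call(rbind, purrr::map(base$arms, "replacement_mix"))
    pooled <- colMeans(mixes)
    for (a in names(base$arms)) base$arms[[a]]$replacement_mix <- pooled
  }
  ov$pooled_replacement_mix <- NULL
  base$settings <- utils::modifyList(base$settings, ov)
  validate_settings(base$settings)
  base
}

#' The packaged scenario suite
#'
#' The standard set of alternative model settings: undiscounted and
#' 5%-discounted analyses, within-trial mortality excluded, direct
#' post-trial treatment effect for 1/3/5 years (and 5 years with linear
#' waning), no treatment discontinuation, the horizon restricted to trial
#' follow-up, a pooled replacement-therapy mix, the societal perspective,
#' and year-1 utilities taken from the health-state utilities instead of
#' the trial EQ-5D trajectory.
#'
#' @return A list of `"cea_scenario"` objects.
#' @export
default_scenarios <- function() {
  list(
    scenario_spec("discount_0pct", discount_cost = 0, discount_benefit = 0),
    scenario_spec("discount_5pct", discount_cost = 0.05, discount_benefit = 0.05),
    scenario_spec("trial_mortality_excluded", include_trial_mortality = FALSE),
    scenario_spec("direct_effect_1y", posttrial_effect_years = 1),
    scenario_spec("direct_effect_3y", posttrial_effect_years = 3),
    scenario_spec("direct_effect_5y", posttrial_effect_years = 5),
    scenario_spec("direct_effect_5y_waning", posttrial_effect_years = 5,
                  posttrial_effect_waning = "linear"),
    scenario_spec("no_discontinuation", apply_discontinuation = FALSE),
    scenario_spec("trial_horizon", horizon_years = 1),
    scenario_spec("pooled_replacement_mix", pooled_replacement_mix = TRUE),
    scenario_spec("societal_perspective", perspective = "societal"),
    scenario_spec("state_utilities_year1", trial_utility_source = "state_utilities")
  )
}

#' Run a suite of scenarios
#'
#' Applies each scenario to the base bundle, re-runs the full pipeline, and
#' reports one row per scenario per comparison; the base case is included
#' as the first row.
#'
#' @param base A `"cea_parameters"` bundle.
#' @param scenarios List of `"cea_scenario"` objects (default
#'   [default_scenarios()]).
#' @param intervention,comparators Arm labels as in [run_cea()].
#' @return A tibble of class `"cea_scenario_suite"`: `scenario`,
#'   comparison columns, deltas, `icer_qaly`, `verdict` and the printable
#'   `icer_label`.
#' @export
run_scenario_suite <- function(base, scenarios = default_scenarios(),
                               intervention = names(base$arms)[1],
                               comparators = setdiff(names(base$arms),
                                                     intervention)) {
  one <- function(label, bundle) {
    res <- run_cea(bundle, intervention, comparators)
    dplyr::mutate(
      res$comparisons[c("intervention", "comparator", "delta_cost",
                        "delta_qaly", "icer_qaly", "verdict",
                        "icer_qaly_label")],
      scenario = label, .before = 1)
  }
  rows <- c(
    list(one("base_case", base)),
    purrr::map(scenarios, function(s) one(s$name, apply_scenario(base, s)))
  )
  out <- dplyr::rename(dplyr::bind_rows(rows), icer_label = "icer_qaly_label")
  class(out) <- c("cea_scenario_suite", class(out))
  out
}
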