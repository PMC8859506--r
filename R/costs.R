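DAYS_PER_YEAR <- 365.25
THIRTY_DAY_UNITS_PER_YEAR <- DAYS_PER_YEAR / 30      # 12.175
HALF_YEAR_30D_UNITS <- 26 * 7 / 30                   # 26 weeks of therapy

#' Annualise a 30-day drug acquisition cost
#'
#' @param cost_per_30d Acquisition cost per 30 days of therapy (GBP).
#' @param fraction_of_year Fraction of the year on therapy, in `[0, 1]`.
#' @return Cost in GBP: `cost_per_30d * (365.25 / 30) * fraction_of_year`.
#' @export
#' @examples
#' annual_drug_cost(44.50)        # full year of triple therapy
annual_drug_cost <- function(cost_per_30d, fraction_of_year = 1) {
  check_range(cost_per_30d, "cost_per_30d", lower = 0)
  check_range(fraction_of_year, "fraction_of_year", 0, 1)
  cost_per_30d * THIRTY_DAY_UNITS_PER_YEAR * fraction_of_year
}

#' Expected year-1 drug plus replacement-therapy cost under discontinuation
#'
#' Patients who discontinue are costed as receiving 26 weeks of their
#' assigned treatment followed by 26 weeks of replacement therapy (26 weeks
#' = 26*7/30 thirty-day units); continuing patients receive a full year of
#' assigned treatment.
#'
#' @param arm_cost_30d Assigned-treatment cost per 30 days (GBP).
#' @param replacement_cost_30d Mix-weighted replacement cost per 30 days (GBP).
#' @param p_disc Proportion discontinuing during the year, in `[0, 1]`.
#' @return A list with components `treatment` and `replacement` (expected
#'   GBP per patient over year 1) and their `total`.
#' @export
discontinuation_cost <- function(arm_cost_30d, replacement_cost_30d, p_disc) {
  check_range(arm_cost_30d, "arm_cost_30d", lower = 0)
  check_range(replacement_cost_30d, "replacement_cost_30d", lower = 0)
  check_range(p_disc, "p_disc", 0, 1)
  treatment <- (1 - p_disc) * arm_cost_30d * THIRTY_DAY_UNITS_PER_YEAR +
    p_disc * arm_cost_30d * HALF_YEAR_30D_UNITS
  replacement <- p_disc * replacement_cost_30d * HALF_YEAR_30D_UNITS
  list(treatment = treatment, replacement = replacement,
       total = treatment + replacement)
}

#' Mix-weighted 30-day replacement-therapy cost
#'
#' Weights the four replacement medication-class costs (LAMA, ICS/LABA,
#' LAMA/LABA, ICS/LAMA/LABA) by an arm's observed post-discontinuation
#' class mix.
#'
#' @param class_costs Numeric vector of 30-day class costs (GBP).
#' @param class_mix Fractions of discontinuing patients per class; must sum
#'   to 1.
#' @return Weighted mean 30-day cost (GBP).
#' @export
replacement_cost_30d <- function(class_costs, class_mix) {
  stopifnot(length(class_costs) == length(class_mix))
  check_range(class_costs, "class_costs", lower = 0)
  check_range(class_mix, "class_mix", 0, 1)
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix must sum to 1 (got ", format(sum(class_mix)), ")",
         call. = FALSE)
  }
  if (!is.null(names(class_costs)) && !is.null(names(class_mix))) {
    class_mix <- class_mix[names(class_costs)]
  }
  sum(class_costs * class_mix)
}

#' Per-event pneumonia cost weighted by the hospitalised fraction
#'
#' @param ambulatory_cost Cost of an ambulatory-managed pneumonia (GBP).
#' @param inpatient_cost Cost of a hospitalised pneumonia (GBP).
#' @param p_hospitalised Proportion of pneumonia cases hospitalised.
#' @return `(1 - p) * ambulatory + p * inpatient` (GBP).
#' @export
pneumonia_event_cost <- function(ambulatory_cost, inpatient_cost, p_hospitalised) {
  check_range(ambulatory_cost, "ambulatory_cost", lower = 0)
  check_range(inpatient_cost, "inpatient_cost", lower = 0)
  check_range(p_hospitalised, "p_hospitalised", 0, 1)
  (1 - p_hospitalised) * ambulatory_cost + p_hospitalised * inpatient_cost
}

# mix-weighted 30-day replacement cost for one arm of a bundle
arm_replacement_30d <- function(bundle, arm) {
  replacement_cost_30d(bundle$costs$replacement_class, arm$replacement_mix)
}
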