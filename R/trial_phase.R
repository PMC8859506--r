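#' Mean utility over the trial year from an EQ-5D trajectory
#'
#' Computes quality-adjustment for year 1 as the trapezoidal area under the
#' piecewise-linear utility curve `baseline + delta(t)` over weeks 0--52,
#' divided by the year length. The trajectory holds change-from-baseline
#' values at scheduled visit weeks; the curve is extended flat before the
#' first and after the last visit, and a missing week-0 point is taken as
#' delta 0 only when no earlier point exists.
#'
#' @param baseline_utility Pooled baseline utility (0--1).
#' @param change_trajectory A data frame with columns `week` (0--52, sorted
#'   increasing) and `delta` (change from baseline), or `NULL`/empty for a
#'   constant baseline.
#' @return Mean utility over the year (QALYs accrued per full life-year
#'   lived in year 1).
#' @export
#' @examples
#' trial_utility_auc(0.787, NULL)  # no measured change: baseline held
trial_utility_auc <- function(baseline_utility, change_trajectory = NULL) {
  check_range(baseline_utility, "baseline_utility", 0, 1)
  if (is.null(change_trajectory) || nrow(change_trajectory) == 0L) {
    return(baseline_utility)
  }
  wk <- change_trajectory$week
  if (is.unsorted(wk, strictly = TRUE)) {
    stop("trajectory weeks must be sorted strictly increasing", call. = FALSE)
  }
  check_range(wk, "week", 0, 52)
  delta <- change_trajectory$delta
  if (wk[1] > 0) { wk <- c(0, wk); delta <- c(delta[1], delta) }
  n <- length(wk)
  if (wk[n] < 52) { wk <- c(wk, 52); delta <- c(delta, delta[n]) }
  u <- baseline_utility + delta
  auc <- sum(diff(wk) * (utils::head(u, -1) + utils::tail(u, -1)) / 2)
  auc / 52
}

#' Run the within-trial decision tree for one arm
#'
#' Accrues year-1 life-years, QALYs and costs per treatment arm directly
#' from 52-week trial outputs. Expected event counts are rates times
#' person-time, where survivors contribute a full year and within-trial
#' decedents half a year. Drug costs follow the discontinuation rule
#' (26 weeks assigned therapy then 26 weeks replacement for discontinuers);
#' maintenance costs are weighted by the trial-end severity mix; event
#' disutilities are subtracted from the utility area under the curve.
#'
#' @param arm One arm entry of a parameter bundle (see [load_parameters()]).
#' @param costs,utilities,settings The matching components of the bundle.
#' @return A list of class `"cea_trial_phase"`: `arm`, `lys`, `qalys`,
#'   `costs` (named category vector, GBP), `events` (named expected
#'   counts), `surviving_fraction`, `person_years`, and
#'   `start_distribution` -- the full 7-state distribution handed to the
#'   Markov phase (living states scaled by survival, death mass attached).
#' @export
run_trial_phase <- function(arm, costs, utilities, settings) {
  p_death <- if (isTRUE(settings$include_trial_mortality)) arm$p_death else 0
  p_disc <- if (isTRUE(settings$apply_discontinuation)) arm$p_discontinuation else 0
  person_years <- 1 - 0.5 * p_death

  events <- c(
    moderate_exac = arm$rate_moderate * person_years,
    severe_exac = arm$rate_severe * person_years,
    pneumonia = arm$p_pneumonia * person_years
  )

  living <- arm$trial_end
  severity_mix <- tapply(living, state_severity(names(living)), sum)[cea_severities()]

  u_mean <- if (identical(settings$trial_utility_source, "state_utilities")) {
    sum(severity_mix * utilities$state)
  } else {
    traj <- utilities$trial_trajectory
    if (!is.null(traj) && "arm" %in% names(traj)) {
      traj <- traj[traj$arm == arm$label, c("week", "delta")]
    }
    trial_utility_auc(utilities$trial_baseline, traj)
  }

  disutility_loss <- sum(events * utilities$disutility[
    c("moderate_exac", "severe_exac", "pneumonia")])
  qalys <- u_mean * person_years - disutility_loss

  repl_30d <- replacement_cost_30d(costs$replacement_class, arm$replacement_mix)
  drug <- discontinuation_cost(arm$drug_cost_30d, repl_30d, p_disc)

  cost_cat <- c(
    treatment = drug$treatment * person_years,
    replacement = drug$replacement * person_years,
    maintenance = sum(severity_mix * costs$maintenance) * person_years,
    moderate_exac = events[["moderate_exac"]] * costs$moderate_exac,
    severe_exac = events[["severe_exac"]] * costs$severe_exac,
    pneumonia = events[["pneumonia"]] * costs$pneumonia,
    societal = 0
  )
  if (identical(settings$perspective, "societal") && !is.null(costs$societal)) {
    cost_cat[["societal"]] <- societal_cost(costs$societal, events,
                                            severity_mix, person_years)
  }

  structure(
    list(
      arm = arm$label,
      lys = person_years,
      qalys = qalys,
      costs = cost_cat,
      events = events,
      surviving_fraction = 1 - p_death,
      person_years = person_years,
      p_discontinued = p_disc,
      replacement_cost_30d = repl_30d,
      start_distribution = full_distribution(living * (1 - p_death), p_death)
    ),
    class = "cea_trial_phase"
  )
}

# productivity losses under the human-capital approach: a cost per event
# plus a cost per severity-year, applied only under the societal perspective
societal_cost <- function(soc, events, severity_mix, person_years) {
  per_event <- c(
    moderate_exac = soc$per_moderate_exac %||% 0,
    severe_exac = soc$per_severe_exac %||% 0,
    pneumonia = soc$per_pneumonia %||% 0
  )
  per_year <- unlist(soc$per_severity_year %||%
                       stats::setNames(rep(0, 3), cea_severities()))[cea_severities()]
  sum(events[names(per_event)] * per_event) +
    sum(severity_mix * per_year) * person_years
}

#' @export
print.cea_trial_phase <- function(x, ...) {
  cat("<cea_trial_phase>", x$arm, "\n")
  cat(sprintf("  LYs %.4f, QALYs %.4f, total cost %.2f (surviving %.4f)\n",
              x$lys, x$qalys, sum(x$costs), x$surviving_fraction))
  invisible(x)
}
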