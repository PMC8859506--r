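#' Per-state annual death probability from background mortality and a
#' severity relative risk
#'
#' Applies the relative risk on the log-survival (rate) scale:
#' `1 - (1 - q)^rr`, clamped to `[0, 1]`.
#'
#' @param background_q Background annual death probability in `[0, 1]`.
#' @param rr Relative risk of mortality (dimensionless, `>= 0`).
#' @return Annual death probability for the state.
#' @export
#' @examples
#' state_death_probability(0.02, 8.33)
state_death_probability <- function(background_q, rr) {
  check_range(background_q, "background_q", 0, 1)
  check_range(rr, "rr", lower = 0)
  pmin(1, pmax(0, 1 - (1 - background_q)^rr))
}

# background q at a (possibly fractional) age: annual life-table convention,
# looked up at floor(age); ages beyond the table are absorbed at the last row
background_q_at <- function(life_table, age) {
  a <- pmin(max(life_table$age), pmax(min(life_table$age), floor(age)))
  life_table$q[match(a, life_table$age)]
}

# 3x3 severity progression matrix (rows: origin, cols: destination),
# upper-triangular by construction: worsening only
progression_matrix <- function(transitions) {
  tr <- transitions[match(cea_severities(), transitions$severity), ]
  P <- diag(3)
  P[1, 2] <- tr$p_to_severe[1]
  P[1, 3] <- tr$p_to_very_severe[1]
  P[2, 3] <- tr$p_to_very_severe[2]
  P[1, 1] <- 1 - P[1, 2] - P[1, 3]
  P[2, 2] <- 1 - P[2, 3]
  dimnames(P) <- list(cea_severities(), cea_severities())
  P
}

# per-living-state exacerbation probabilities in cea_living_states() order
exac_by_state <- function(exacerbation) {
  key <- paste(exacerbation$severity, exacerbation$stratum, sep = ".")
  idx <- match(cea_living_states(), key)
  list(p_moderate = exacerbation$p_moderate[idx],
       p_severe = exacerbation$p_severe[idx])
}

#' Split next-cycle survivors between exacerbation-history strata
#'
#' A fraction `p_any_exac` of each origin state's survivors (who may have
#' progressed in severity) enters the recent-exacerbation stratum of its
#' destination severity; the remainder enters the no-recent stratum.
#'
#' @param p_any_exac Probability of at least one (moderate or severe)
#'   exacerbation during the cycle, per origin state.
#' @param survivors_by_severity For one origin state: surviving mass per
#'   destination severity (length-3 vector, [cea_severities()] order).
#' @return Named length-6 occupancy increment over the living states.
#' @export
exacerbation_stratum_update <- function(p_any_exac, survivors_by_severity) {
  check_range(p_any_exac, "p_any_exac", 0, 1)
  out <- stats::setNames(numeric(6L), cea_living_states())
  out[paste(cea_severities(), "no_recent", sep = ".")] <-
    survivors_by_severity * (1 - p_any_exac)
  out[paste(cea_severities(), "recent", sep = ".")] <-
    survivors_by_severity * p_any_exac
  out
}

#' Advance the cohort by one annual Markov cycle
#'
#' Order of operations within a cycle: (1) state-specific death from the
#' age-specific background probability scaled by the severity relative
#' risk; (2) severity progression among survivors (worsening only);
#' (3) exacerbation expectation from origin-state risks applied to
#' survivors; (4) history-stratum update at the destination severity.
#' Occupancy is conserved to numerical precision.
#'
#' @param d Full 7-state cohort distribution (see [validate_distribution()]).
#' @param trans_model List with `transitions` and `exacerbation` tables of a
#'   parameter bundle.
#' @param mortality Mortality component of a bundle (`life_table`, `rr`).
#' @param age Cohort age (years) at the start of the cycle.
#' @return List: `distribution` (next 7-state distribution),
#'   `deaths_by_state`, `survivors` (total living after the death step), and
#'   `events` (expected counts: `moderate_exac`, `severe_exac`).
#' @export
run_cycle <- function(d, trans_model, mortality, age) {
  if (!identical(names(d), STATES7)) {
    chk <- validate_distribution(d)
    if (!chk$valid) stop("invalid cohort distribution entering run_cycle",
                         call. = FALSE)
    d <- d[STATES7]
  } else if (any(d < -1e-9) || abs(sum(d) - 1) > 1e-9) {
    stop("invalid cohort distribution entering run_cycle", call. = FALSE)
  }

  living <- d[1:6]
  q_bg <- background_q_at(mortality$life_table, age)
  q_state <- state_death_probability(q_bg, mortality$rr[SEV_IDX6])
  deaths <- living * q_state
  survivors <- living - deaths

  P <- progression_matrix(trans_model$transitions)
  ex <- exac_by_state(trans_model$exacerbation)
  p_any <- 1 - (1 - ex$p_moderate) * (1 - ex$p_severe)

  # destination-severity mass per history stratum (vectorised stratum update)
  M <- P[SEV_IDX6, , drop = FALSE]                  # 6 origins x 3 destinations
  dest_nr <- as.vector(crossprod(M, survivors * (1 - p_any)))
  dest_r <- as.vector(crossprod(M, survivors * p_any))
  nxt_living <- stats::setNames(as.vector(rbind(dest_nr, dest_r)), LIVING6)

  events <- c(moderate_exac = sum(survivors * ex$p_moderate),
              severe_exac = sum(survivors * ex$p_severe))

  nxt <- c(nxt_living, death = unname(d[["death"]] + sum(deaths)))
  list(distribution = nxt, deaths_by_state = deaths,
       survivors = sum(survivors), events = events)
}

#' Scale post-trial exacerbation probabilities by a direct treatment effect
#'
#' In the base case no direct treatment effect persists beyond the trial
#' (`rate_reduction = 0`); scenario analyses apply the within-trial
#' exacerbation rate reduction for 1, 3 or 5 post-trial years, either at
#' full strength throughout (`waning = "none"`) or declining linearly to
#' zero over the duration (`waning = "linear"`).
#'
#' @param trans_model List with `transitions` and `exacerbation` tables.
#' @param rate_reduction Fractional reduction in exacerbation probabilities
#'   while the effect lasts, in `[0, 1]`.
#' @param cycle_index 0-based post-trial cycle index.
#' @param duration_years Years the effect lasts.
#' @param waning `"none"` or `"linear"`.
#' @return The model with `p_moderate`/`p_severe` scaled; transitions are
#'   untouched.
#' @export
apply_posttrial_effect <- function(trans_model, rate_reduction, cycle_index,
                                   duration_years, waning = c("none", "linear")) {
  waning <- match.arg(waning)
  check_range(rate_reduction, "rate_reduction", 0, 1)
  if (rate_reduction == 0 || duration_years <= 0 || cycle_index >= duration_years) {
    return(trans_model)
  }
  eff <- if (waning == "linear") {
    rate_reduction * (1 - cycle_index / duration_years)
  } else {
    rate_reduction
  }
  trans_model$exacerbation$p_moderate <- trans_model$exacerbation$p_moderate * (1 - eff)
  trans_model$exacerbation$p_severe <- trans_model$exacerbation$p_severe * (1 - eff)
  trans_model
}

#' Run the post-trial Markov cohort model to the horizon
#'
#' Starts from the trial-end distribution (living states scaled by trial
#' survival) and runs `horizon_years - 1` annual cycles. Per cycle it
#' accrues undiscounted life-years, QALYs and costs by category;
#' within-cycle decedents contribute half a cycle of life-year, QALY,
#' maintenance and drug-cost accrual (person-time convention). Pneumonia
#' expectation is the arm's annual probability times the surviving
#' fraction; drug and replacement costs accrue over person-time with the
#' discontinuation status fixed at trial end (discontinued patients stay on
#' replacement therapy for the remaining horizon).
#'
#' @param start Full 7-state distribution at trial end (from
#'   [run_trial_phase()]'s `start_distribution`).
#' @param params A `"cea_parameters"` bundle.
#' @param arm One arm entry of the bundle.
#' @param settings Model settings (defaults to `params$settings`).
#' @param effect_overrides Optional list (`rate_reduction`,
#'   `duration_years`, `waning`) applying a direct post-trial effect to this
#'   arm; see [apply_posttrial_effect()].
#' @param p_discontinued Fraction on replacement therapy, fixed at trial
#'   end; defaults to the arm's (possibly scenario-disabled) value.
#' @return A `"cea_markov_trace"` tibble, one row per post-trial cycle:
#'   cycle index (1-based model year), cohort age, the seven occupancy
#'   columns at the *start* of the cycle, expected events, and undiscounted
#'   `ly`, `qaly` and `cost_*` accruals for the cycle.
#' @export
run_markov <- function(start, params, arm, settings = params$settings,
                       effect_overrides = NULL, p_discontinued = NULL) {
  n_cycles <- as.integer(settings$horizon_years) - 1L
  if (is.null(p_discontinued)) {
    p_discontinued <- if (isTRUE(settings$apply_discontinuation)) {
      arm$p_discontinuation
    } else {
      0
    }
  }
  repl_annual <- annual_drug_cost(arm_replacement_30d(params, arm))
  drug_annual <- annual_drug_cost(arm$drug_cost_30d)
  u_state <- params$utilities$state[match(state_severity(), cea_severities())]
  c_maint <- params$costs$maintenance[match(state_severity(), cea_severities())]
  du <- params$utilities$disutility
  base_model <- list(transitions = params$transitions,
                     exacerbation = params$exacerbation)
  societal_on <- identical(settings$perspective, "societal") &&
    !is.null(params$costs$societal)

  col_names <- c("cycle", "age", paste0("occ_", cea_states()),
                 "events_moderate", "events_severe", "events_pneumonia",
                 "ly", "qaly",
                 paste0("cost_", c("treatment", "replacement", "maintenance",
                                   "moderate_exac", "severe_exac", "pneumonia",
                                   "societal")))
  acc <- matrix(0, nrow = max(n_cycles, 0L), ncol = length(col_names),
                dimnames = list(NULL, col_names))
  d <- start[cea_states()]
  for (k in seq_len(n_cycles)) {
    age <- settings$start_age + k
    model <- base_model
    if (!is.null(effect_overrides)) {
      model <- apply_posttrial_effect(
        model, effect_overrides$rate_reduction, k - 1L,
        effect_overrides$duration_years,
        effect_overrides$waning %||% "none")
    }
    step <- run_cycle(d, model, params$mortality, age)

    living <- d[cea_living_states()]
    deaths <- step$deaths_by_state
    pt_by_state <- living - 0.5 * deaths       # person-time per origin state
    pt <- sum(pt_by_state)
    ev <- step$events
    ev_pneu <- arm$p_pneumonia * step$survivors

    qaly <- sum(pt_by_state * u_state) -
      ev[["moderate_exac"]] * du[["moderate_exac"]] -
      ev[["severe_exac"]] * du[["severe_exac"]] -
      ev_pneu * du[["pneumonia"]]

    cost <- c(
      treatment = (1 - p_discontinued) * drug_annual * pt,
      replacement = p_discontinued * repl_annual * pt,
      maintenance = sum(pt_by_state * c_maint),
      moderate_exac = ev[["moderate_exac"]] * params$costs$moderate_exac,
      severe_exac = ev[["severe_exac"]] * params$costs$severe_exac,
      pneumonia = ev_pneu * params$costs$pneumonia,
      societal = 0
    )
    if (societal_on) {
      sev_mix <- tapply(pt_by_state, state_severity(), sum)[cea_severities()]
      cost[["societal"]] <- societal_cost(
        params$costs$societal,
        c(moderate_exac = ev[["moderate_exac"]],
          severe_exac = ev[["severe_exac"]], pneumonia = ev_pneu),
        sev_mix / max(pt, .Machine$double.eps), pt)
    }

    acc[k, ] <- c(k, age, d, ev[["moderate_exac"]], ev[["severe_exac"]],
                  ev_pneu, pt, qaly, cost)
    d <- step$distribution
  }
  trace <- tibble::as_tibble(acc)
  trace$cycle <- as.integer(trace$cycle)
  attr(trace, "final_distribution") <- d
  class(trace) <- c("cea_markov_trace", class(trace))
  trace
}
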