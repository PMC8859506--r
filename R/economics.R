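#' Discount a per-cycle stream to present value
#'
#' The trial year is discount period 0 (undiscounted); Markov cycle `k`
#' is discounted by `1 / (1 + rate)^k`.
#'
#' @param values Per-period amounts.
#' @param rate Annual discount rate (fraction, `>= 0`).
#' @param periods Integer period indices (default `0, 1, 2, ...`).
#' @return The discounted total.
#' @export
#' @examples
#' discount_stream(c(100, 100, 100), 0.035)
discount_stream <- function(values, rate, periods = seq_along(values) - 1) {
  check_range(rate, "rate", lower = 0)
  stopifnot(length(values) == length(periods))
  sum(values / (1 + rate)^periods)
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' An intervention is *dominant* when it is more effective and less costly
#' (no ratio reported), *dominated* when less effective and more costly.
#' Otherwise the ICER is the finite ratio of unrounded incrementals. A zero
#' effect difference with a nonzero cost difference yields an undefined
#' ratio labelled by the sign of the cost difference.
#'
#' @param delta_cost Incremental cost (intervention minus comparator, GBP).
#' @param delta_effect Incremental effect (QALYs or LYs).
#' @return A list: `delta_cost`, `delta_effect`, `icer` (GBP per effect
#'   unit, `NA` when no ratio applies), and `verdict` -- one of `"icer"`,
#'   `"dominant"`, `"dominated"`, `"undefined_costlier"`,
#'   `"undefined_cheaper"`, `"equivalent"`.
#' @export
#' @examples
#' compute_icer(1129, 0.275)
compute_icer <- function(delta_cost, delta_effect) {
  verdict <- if (delta_effect > 0 && delta_cost < 0) {
    "dominant"
  } else if (delta_effect < 0 && delta_cost > 0) {
    "dominated"
  } else if (delta_effect == 0 && delta_cost != 0) {
    if (delta_cost > 0) "undefined_costlier" else "undefined_cheaper"
  } else if (delta_effect == 0 && delta_cost == 0) {
    "equivalent"
  } else {
    "icer"
  }
  icer <- if (identical(verdict, "icer")) delta_cost / delta_effect else NA_real_
  list(delta_cost = delta_cost, delta_effect = delta_effect,
       icer = icer, verdict = verdict)
}

# printable ICER: "dominant"/"dominated" in place of a ratio, never negative
format_icer <- function(cmp) {
  if (identical(cmp$verdict, "icer")) sprintf("%.0f", cmp$icer) else cmp$verdict
}

COST_CATEGORIES <- c("maintenance", "moderate_exac", "severe_exac",
                     "pneumonia", "treatment", "replacement", "societal")

#' Aggregate trial-phase and Markov accruals into per-arm totals
#'
#' Category-wise discounted and undiscounted sums over the trial year
#' (period 0) and the post-trial Markov cycles (periods 1, 2, ...), using
#' the cost and benefit discount rates of `settings`. Expected event
#' counts are lifetime sums, undiscounted, trial year included.
#'
#' @param trial A `"cea_trial_phase"` result.
#' @param trace The matching `"cea_markov_trace"`.
#' @param settings Model settings.
#' @return A list of class `"cea_economics"`: `arm`, `discounted` and
#'   `undiscounted` (named vectors: `lys`, `qalys`, one entry per cost
#'   category, `total_cost`), and `events`.
#' @export
assemble_results <- function(trial, trace, settings) {
  if (!is.null(attr(trace, "arm")) && !identical(attr(trace, "arm"), trial$arm)) {
    stop("trial-phase and Markov results belong to different arms", call. = FALSE)
  }
  periods <- c(0, trace$cycle)
  rc <- settings$discount_cost
  rb <- settings$discount_benefit

  totals <- function(rate_costs, rate_benefits) {
    cat_sums <- vapply(COST_CATEGORIES, function(cat) {
      discount_stream(c(trial$costs[[cat]], trace[[paste0("cost_", cat)]]),
                      rate_costs, periods)
    }, numeric(1))
    c(lys = discount_stream(c(trial$lys, trace$ly), rate_benefits, periods),
      qalys = discount_stream(c(trial$qalys, trace$qaly), rate_benefits, periods),
      cat_sums,
      total_cost = sum(cat_sums))
  }

  events <- c(
    moderate_exac = trial$events[["moderate_exac"]] + sum(trace$events_moderate),
    severe_exac = trial$events[["severe_exac"]] + sum(trace$events_severe),
    pneumonia = trial$events[["pneumonia"]] + sum(trace$events_pneumonia)
  )
  events["any_exac"] <- events[["moderate_exac"]] + events[["severe_exac"]]

  structure(
    list(arm = trial$arm,
         discounted = totals(rc, rb),
         undiscounted = totals(0, 0),
         events = events),
    class = "cea_economics"
  )
}

#' Run the full cost-effectiveness pipeline
#'
#' For every arm in the bundle: within-trial decision tree, post-trial
#' Markov extrapolation, discounted aggregation; then pairwise incremental
#' comparisons of the intervention against each comparator.
#'
#' When `settings$posttrial_effect_years > 0`, the intervention arm is
#' re-run per comparison with a direct post-trial exacerbation effect whose
#' rate reduction is the within-trial reduction in the combined
#' (moderate + severe) exacerbation rate relative to that comparator.
#'
#' @param params A `"cea_parameters"` bundle.
#' @param intervention Arm label of the intervention (default: first arm).
#' @param comparators Arm labels to compare against (default: all others).
#' @param settings Optional settings override (defaults to the bundle's).
#' @return A list of class `"cea_result"`: `arms` (per-arm
#'   `"cea_economics"`), `trial`, `traces`, `comparisons` (a tibble with
#'   deltas, ICERs per QALY and per LY, and the dominance verdict), and
#'   `settings`. Use [tidy()][generics::tidy] / [glance()][generics::glance]
#'   and [cea_table()] on it.
#' @export
run_cea <- function(params, intervention = names(params$arms)[1],
                    comparators = setdiff(names(params$arms), intervention),
                    settings = params$settings) {
  stopifnot(inherits(params, "cea_parameters"))
  if (!intervention %in% names(params$arms)) {
    stop("unknown intervention arm '", intervention, "'", call. = FALSE)
  }

  run_arm <- function(label, effect_overrides = NULL) {
    arm <- params$arms[[label]]
    trial <- run_trial_phase(arm, params$costs, params$utilities, settings)
    trace <- run_markov(trial$start_distribution, params, arm, settings,
                        effect_overrides = effect_overrides,
                        p_discontinued = trial$p_discontinued)
    list(trial = trial, trace = trace,
         econ = assemble_results(trial, trace, settings))
  }

  base_runs <- lapply(stats::setNames(nm = names(params$arms)), run_arm)

  effect_years <- settings$posttrial_effect_years %||% 0
  cmp_rows <- purrr::map(comparators, function(comp) {
    int_run <- base_runs[[intervention]]
    if (effect_years > 0) {
      a_int <- params$arms[[intervention]]
      a_cmp <- params$arms[[comp]]
      r_int <- a_int$rate_moderate + a_int$rate_severe
      r_cmp <- a_cmp$rate_moderate + a_cmp$rate_severe
      reduction <- max(0, min(1, 1 - r_int / r_cmp))
      int_run <- run_arm(intervention, effect_overrides = list(
        rate_reduction = reduction,
        duration_years = effect_years,
        waning = settings$posttrial_effect_waning %||% "none"))
    }
    ei <- int_run$econ$discounted
    ec <- base_runs[[comp]]$econ$discounted
    dq <- ei[["qalys"]] - ec[["qalys"]]
    dl <- ei[["lys"]] - ec[["lys"]]
    dc <- ei[["total_cost"]] - ec[["total_cost"]]
    icq <- compute_icer(dc, dq)
    icl <- compute_icer(dc, dl)
    tibble::tibble(
      intervention = intervention, comparator = comp,
      delta_cost = dc, delta_qaly = dq, delta_ly = dl,
      icer_qaly = icq$icer, icer_ly = icl$icer,
      verdict = icq$verdict,
      icer_qaly_label = format_icer(icq), icer_ly_label = format_icer(icl)
    )
  })

  structure(
    list(
      arms = purrr::map(base_runs, "econ"),
      trial = purrr::map(base_runs, "trial"),
      traces = purrr::map(base_runs, "trace"),
      comparisons = dplyr::bind_rows(cmp_rows),
      intervention = intervention,
      settings = settings
    ),
    class = "cea_result"
  )
}

#' Results table in the standard reporting layout
#'
#' One row per quantity (expected exacerbations, discounted LYs and QALYs,
#' cost categories, totals, ICERs), one column per arm plus one per
#' pairwise increment -- the layout of a published cost-effectiveness
#' results table.
#'
#' @param result A `"cea_result"`.
#' @return A tibble; ICER rows hold the ratio, or `NA` with the verdict in
#'   the matching label row of [glance()][generics::glance].
#' @export
cea_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  arms <- result$arms
  quantity <- c("moderate_exacerbations", "severe_exacerbations",
                "any_exacerbation", "lys_discounted", "qalys_discounted",
                paste0("cost_", COST_CATEGORIES), "total_cost")
  per_arm <- function(e) {
    unname(c(e$events[["moderate_exac"]], e$events[["severe_exac"]],
             e$events[["any_exac"]], e$discounted[["lys"]],
             e$discounted[["qalys"]], e$discounted[COST_CATEGORIES],
             e$discounted[["total_cost"]]))
  }
  tab <- tibble::tibble(quantity = quantity)
  for (nm in names(arms)) tab[[nm]] <- per_arm(arms[[nm]])
  for (i in seq_len(nrow(result$comparisons))) {
    cmp <- result$comparisons[i, ]
    col <- paste0(cmp$intervention, "_vs_", cmp$comparator)
    tab[[col]] <- tab[[cmp$intervention]] - tab[[cmp$comparator]]
  }
  tab
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>", length(x$arms), "arms,",
      nrow(x$comparisons), "comparisons\n")
  for (i in seq_len(nrow(x$comparisons))) {
    cmp <- x$comparisons[i, ]
    cat(sprintf("  %s vs %s: dCost %.0f, dQALY %.4f, ICER/QALY %s\n",
                cmp$intervention, cmp$comparator, cmp$delta_cost,
                cmp$delta_qaly, cmp$icer_qaly_label))
  }
  invisible(x)
}
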