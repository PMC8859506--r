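# Fixtures built in code: a flat-mortality life table, a hand-traceable
# "toy" parameter bundle occupying only two severities, and an independent
# straight-line oracle for the Markov accounting conventions.

flat_life_table <- function(q = 0.1) {
  tibble::tibble(age = 40:110, q = q)
}

make_arm <- function(label = "A",
                     drug_cost_30d = 30,
                     rate_moderate = 0, rate_severe = 0,
                     p_pneumonia = 0, p_death = 0, p_discontinuation = 0,
                     replacement_mix = c(lama = 0.25, ics_laba = 0.25,
                                         lama_laba = 0.25, ics_lama_laba = 0.25),
                     trial_end = c(moderate.no_recent = 1, moderate.recent = 0,
                                   severe.no_recent = 0, severe.recent = 0,
                                   very_severe.no_recent = 0,
                                   very_severe.recent = 0)) {
  list(label = label, drug_cost_30d = drug_cost_30d,
       rate_moderate = rate_moderate, rate_severe = rate_severe,
       p_pneumonia = p_pneumonia, p_death = p_death,
       p_discontinuation = p_discontinuation,
       replacement_mix = replacement_mix,
       trial_end = trial_end[copdcea::cea_living_states()])
}

# toy bundle: cohort confined to {moderate, severe} (no inflow to very
# severe), flat background mortality q, uniform mortality RR, single
# progression probability, stratum-constant moderate-exacerbation risk
toy_bundle <- function(q = 0.1, rr = 2, progression = 0.2, p_exac = 0.3,
                       arms = list(A = make_arm()), horizon = 3,
                       u = c(moderate = 0.8, severe = 0.7, very_severe = 0.6),
                       rr_vec = NULL) {
  settings <- modifyList(copdcea:::default_settings(),
                         list(horizon_years = horizon, start_age = 65,
                              discount_cost = 0, discount_benefit = 0))
  bundle <- structure(list(
    transitions = tibble::tibble(
      severity = copdcea::cea_severities(),
      p_to_severe = c(progression, 0, 0),
      p_to_very_severe = c(0, 0, 0)),
    exacerbation = tibble::tibble(
      severity = rep(copdcea::cea_severities(), each = 2),
      stratum = rep(c("no_recent", "recent"), 3),
      p_moderate = p_exac, p_severe = 0),
    mortality = list(life_table = flat_life_table(q),
                     rr = rr_vec %||% c(moderate = rr, severe = rr,
                                        very_severe = rr)),
    costs = list(maintenance = c(moderate = 100, severe = 200,
                                 very_severe = 300),
                 moderate_exac = 568.48, severe_exac = 6120.30,
                 pneumonia = 1087.98,
                 replacement_class = c(lama = 29.29, ics_laba = 31.79,
                                       lama_laba = 32.50,
                                       ics_lama_laba = 61.08),
                 societal = NULL),
    utilities = list(state = u,
                     disutility = c(moderate_exac = 0.011,
                                    severe_exac = 0.020, pneumonia = 0.011),
                     trial_baseline = 0.75, trial_trajectory = NULL,
                     state_ci = NULL, disutility_ci = NULL),
    arms = arms,
    settings = settings,
    meta = list(provenance = "toy fixture")
  ), class = "cea_parameters")
  copdcea::validate_parameters(bundle)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent straight-line oracle for the toy dynamics: scalar spreadsheet
# arithmetic over the states (m = moderate, s = severe), mirroring the
# documented conventions (death -> progression -> events -> stratum split;
# decedents credited half a cycle) without using any engine code.
toy_hand_trace <- function(n_cycles, q = 0.1, rr = 2, progression = 0.2,
                           p_exac = 0.3, u_m = 0.8, u_s = 0.7,
                           du = 0.011, start = c(m_nr = 1, m_r = 0,
                                                 s_nr = 0, s_r = 0)) {
  qs <- 1 - (1 - q)^rr
  m_nr <- start[["m_nr"]]; m_r <- start[["m_r"]]
  s_nr <- start[["s_nr"]]; s_r <- start[["s_r"]]
  dead <- 1 - m_nr - m_r - s_nr - s_r
  out <- list()
  for (k in seq_len(n_cycles)) {
    m <- m_nr + m_r; s <- s_nr + s_r
    deaths_m <- m * qs; deaths_s <- s * qs
    surv_m <- m - deaths_m; surv_s <- s - deaths_s
    events <- (surv_m + surv_s) * p_exac
    to_s <- surv_m * progression
    stay_m <- surv_m - to_s
    new_s <- surv_s + to_s
    m_nr <- stay_m * (1 - p_exac); m_r <- stay_m * p_exac
    s_nr <- new_s * (1 - p_exac); s_r <- new_s * p_exac
    dead <- dead + deaths_m + deaths_s
    pt_m <- m - 0.5 * deaths_m
    pt_s <- s - 0.5 * deaths_s
    out[[k]] <- c(
      cycle = k,
      m = m_nr + m_r, s = s_nr + s_r, dead = dead,
      events = events,
      ly = pt_m + pt_s,
      qaly = pt_m * u_m + pt_s * u_s - events * du,
      maintenance = pt_m * 100 + pt_s * 200
    )
  }
  as.data.frame(do.call(rbind, out))
}

base_bundle <- function() copdcea::load_parameters(copdcea::cea_base_config())
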