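start_all_moderate <- function() {
  stats::setNames(c(1, 0, 0, 0, 0, 0, 0), cea_states())
}

test_that("state death probability multiplies hazards on the log-survival scale", {
  expect_equal(state_death_probability(0.02, 1), 0.02)
  expect_equal(state_death_probability(0.02, 8.33),
               1 - exp(8.33 * log(0.98)))
  expect_equal(state_death_probability(0.02, 8.33), 0.1550, tolerance = 1e-3)
  expect_equal(state_death_probability(0, 5), 0)
  expect_equal(state_death_probability(1, 0.5), 1)
})

test_that("stratum update routes exacerbating survivors to the recent stratum", {
  sv <- c(0.5, 0.3, 0.2)
  none <- exacerbation_stratum_update(0, sv)
  expect_equal(unname(none[paste0(cea_severities(), ".no_recent")]), sv)
  expect_equal(sum(none[paste0(cea_severities(), ".recent")]), 0)

  all <- exacerbation_stratum_update(1, sv)
  expect_equal(unname(all[paste0(cea_severities(), ".recent")]), sv)

  split <- exacerbation_stratum_update(0.4, c(1, 0, 0))
  expect_equal(split[["moderate.recent"]], 0.4)
  expect_equal(split[["moderate.no_recent"]], 0.6)
})

test_that("a cycle with identity transitions and no mortality only re-strata", {
  b <- toy_bundle(q = 0, progression = 0, p_exac = 0.3)
  step <- run_cycle(start_all_moderate(),
                    list(transitions = b$transitions,
                         exacerbation = b$exacerbation),
                    b$mortality, 65)
  expect_equal(step$distribution[["moderate.no_recent"]], 0.7)
  expect_equal(step$distribution[["moderate.recent"]], 0.3)
  expect_equal(step$distribution[["death"]], 0)
  expect_equal(sum(step$distribution), 1, tolerance = 1e-12)
})

test_that("an all-death cohort stays dead with zero events", {
  b <- toy_bundle()
  dead <- stats::setNames(c(rep(0, 6), 1), cea_states())
  step <- run_cycle(dead, list(transitions = b$transitions,
                               exacerbation = b$exacerbation),
                    b$mortality, 70)
  expect_equal(step$distribution, dead)
  expect_equal(unname(step$events), c(0, 0))
  expect_error(run_cycle(dead * 0.9, list(transitions = b$transitions,
                                          exacerbation = b$exacerbation),
                         b$mortality, 70),
               "invalid cohort distribution")
})

test_that("the two-cycle toy trace matches the hand-computed oracle to 1e-12", {
  b <- toy_bundle(q = 0.1, rr = 2, progression = 0.2, p_exac = 0.3,
                  horizon = 3)
  trace <- run_markov(start_all_moderate(), b, b$arms$A)
  oracle <- toy_hand_trace(2)

  # frozen hand-computed values, cycle 1 then cycle 2:
  # deaths 0.19 -> survivors 0.81; progression 0.2; stratum split 0.3
  expect_equal(oracle$dead, c(0.19, 0.3439), tolerance = 1e-15)
  expect_equal(oracle$s, c(0.162, 0.236196), tolerance = 1e-15)
  expect_equal(oracle$events, c(0.243, 0.19683), tolerance = 1e-15)
  expect_equal(oracle$ly, c(0.905, 0.73305), tolerance = 1e-15)

  # the trace records occupancy at the start of each cycle; the oracle
  # reports end-of-cycle state, so compare against the next cycle's start
  final <- attr(trace, "final_distribution")
  expect_equal(c(trace$occ_death[-1], final[["death"]]), oracle$dead,
               tolerance = 1e-12)
  expect_equal(c(trace$occ_severe.no_recent[-1] + trace$occ_severe.recent[-1],
                 final[["severe.no_recent"]] + final[["severe.recent"]]),
               oracle$s, tolerance = 1e-12)
  expect_equal(trace$events_moderate, oracle$events, tolerance = 1e-12)
  expect_equal(trace$ly, oracle$ly, tolerance = 1e-12)
  expect_equal(trace$qaly, oracle$qaly, tolerance = 1e-12)
  expect_equal(trace$cost_maintenance, oracle$maintenance, tolerance = 1e-12)
})

test_that("engine totals equal a matrix-power oracle on the collapsed severity chain", {
  # severity dynamics decouple from the history strata when risks are
  # stratum-constant, so a 4-state (3 severities + death) matrix-power model
  # must reproduce the engine's totals
  q <- 0.05; rr <- c(1, 2, 4); p_ms <- 0.2; p_sv <- 0.3; p_exac <- 0.3
  b <- toy_bundle(q = q, progression = p_ms, p_exac = p_exac, horizon = 21,
                  rr_vec = c(moderate = 1, severe = 2, very_severe = 4))
  b$transitions$p_to_very_severe <- c(0, p_sv, 0)
  validate_parameters(b)

  start <- stats::setNames(c(0.5, 0, 0.3, 0, 0.2, 0, 0), cea_states())
  trace <- run_markov(start, b, b$arms$A)

  qs <- 1 - (1 - q)^rr
  A <- rbind(
    c((1 - qs[1]) * (1 - p_ms), (1 - qs[1]) * p_ms, 0, qs[1]),
    c(0, (1 - qs[2]) * (1 - p_sv), (1 - qs[2]) * p_sv, qs[2]),
    c(0, 0, 1 - qs[3], qs[3]),
    c(0, 0, 0, 1)
  )
  occ <- c(0.5, 0.3, 0.2, 0)
  u <- c(0.8, 0.7, 0.6)
  ly <- qaly <- events <- 0
  for (k in 1:20) {
    deaths <- occ[1:3] * qs
    pt <- occ[1:3] - 0.5 * deaths
    surv <- occ[1:3] - deaths
    ly <- ly + sum(pt)
    qaly <- qaly + sum(pt * u) - sum(surv) * p_exac * 0.011
    events <- events + sum(surv) * p_exac
    occ <- as.vector(occ %*% A)
  }
  expect_equal(sum(trace$ly), ly, tolerance = 1e-10)
  expect_equal(sum(trace$qaly), qaly, tolerance = 1e-10)
  expect_equal(sum(trace$events_moderate), events, tolerance = 1e-10)
  expect_equal(trace$occ_death[20] + sum(trace[20, paste0("occ_", cea_living_states())]),
               1, tolerance = 1e-12)
})

test_that("occupancy is conserved and death is monotone under random dynamics", {
  set.seed(42)
  for (rep in 1:5) {
    p_nr <- sort(runif(3, 0.1, 0.6))
    mult <- runif(1, 1, 1.4)
    b <- toy_bundle(q = runif(1, 0.01, 0.2), progression = runif(1, 0, 0.5),
                    horizon = 16)
    b$exacerbation$p_moderate <- as.vector(rbind(p_nr, pmin(0.97, p_nr * mult)))
    b$exacerbation$p_severe <- as.vector(rbind(p_nr / 4, pmin(1, p_nr * mult) / 4))
    b$transitions$p_to_very_severe <- c(0, runif(1, 0, 0.4), 0)
    validate_parameters(b)

    d0 <- runif(7); d0 <- d0 / sum(d0)
    names(d0) <- cea_states()
    trace <- run_markov(d0, b, b$arms$A)
    occ <- as.matrix(trace[paste0("occ_", cea_states())])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(diff(trace$occ_death) >= -1e-12))
    # progression-only dynamics: total moderate occupancy never increases
    mod <- trace$occ_moderate.no_recent + trace$occ_moderate.recent
    expect_true(all(diff(mod) <= 1e-12))
  }
})

test_that("raising any severity's mortality RR weakly decreases total LYs", {
  b <- toy_bundle(q = 0.05, progression = 0.15, horizon = 21,
                  rr_vec = c(moderate = 1.89, severe = 3.63,
                             very_severe = 8.33))
  start <- stats::setNames(c(0.4, 0, 0.4, 0, 0.2, 0, 0), cea_states())
  ly_of <- function(bundle) sum(run_markov(start, bundle, bundle$arms$A)$ly)
  base_ly <- ly_of(b)
  for (s in cea_severities()) {
    up <- b; up$mortality$rr[[s]] <- up$mortality$rr[[s]] * 1.2
    dn <- b; dn$mortality$rr[[s]] <- max(1, dn$mortality$rr[[s]] * 0.8)
    expect_lte(ly_of(up), base_ly + 1e-12)
    expect_gte(ly_of(dn), base_ly - 1e-12)
  }
})

test_that("extreme mortality leaves only the half-cycle credit beyond the trial", {
  b <- toy_bundle(q = 1, horizon = 6)   # certain death each cycle
  trace <- run_markov(start_all_moderate(), b, b$arms$A)
  expect_equal(trace$ly[1], 0.5)
  expect_equal(sum(trace$ly), 0.5)
  expect_equal(trace$occ_death[2], 1)
})

test_that("zero mortality and zero discounting accrue the full horizon", {
  b <- toy_bundle(q = 0, horizon = 35)
  trace <- run_markov(start_all_moderate(), b, b$arms$A)
  expect_equal(sum(trace$ly), 34)    # plus 1 trial year = 35
  tp <- run_trial_phase(b$arms$A, b$costs, b$utilities, b$settings)
  econ <- assemble_results(tp, trace, b$settings)
  expect_equal(econ$discounted[["lys"]], 35, tolerance = 1e-12)
})

test_that("post-trial treatment effect scales exacerbation risk and then expires", {
  b <- toy_bundle()
  tm <- list(transitions = b$transitions, exacerbation = b$exacerbation)

  expect_identical(apply_posttrial_effect(tm, 0, 0, 5), tm)

  eff <- apply_posttrial_effect(tm, 0.4, 0, 5)
  expect_equal(eff$exacerbation$p_moderate, tm$exacerbation$p_moderate * 0.6)
  expect_identical(eff$transitions, tm$transitions)

  # linear waning at half duration applies half the reduction
  half <- apply_posttrial_effect(tm, 0.4, 2.5, 5, waning = "linear")
  expect_equal(half$exacerbation$p_moderate,
               tm$exacerbation$p_moderate * (1 - 0.2))

  expired <- apply_posttrial_effect(tm, 0.4, 5, 5)
  expect_identical(expired, tm)
})
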