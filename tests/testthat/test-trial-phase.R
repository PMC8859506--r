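test_that("drug-cost annualisation follows the 30-day pricing convention", {
  expect_equal(annual_drug_cost(44.50, 1.0), 44.50 * 365.25 / 30)
  expect_equal(annual_drug_cost(44.50, 1.0), 541.79, tolerance = 1e-4)
  expect_equal(annual_drug_cost(0, 1.0), 0)
  expect_equal(annual_drug_cost(22.00, 0.5), 133.93, tolerance = 1e-4)
  expect_error(annual_drug_cost(-1), "cost_per_30d")
  expect_error(annual_drug_cost(10, 1.5), "fraction_of_year")
})

test_that("discontinuation costing mixes 26 weeks of assigned and replacement therapy", {
  none <- discontinuation_cost(44.50, 48.01, 0)
  expect_equal(none$total, annual_drug_cost(44.50))
  expect_equal(none$replacement, 0)

  all <- discontinuation_cost(44.50, 48.01, 1)
  expect_equal(all$total, 26 * 7 / 30 * (44.50 + 48.01))
  expect_equal(all$total, 561.23, tolerance = 1e-2)

  # linearity in the discontinuation proportion
  half <- discontinuation_cost(44.50, 48.01, 0.5)
  expect_equal(half$total, (none$total + all$total) / 2, tolerance = 1e-12)
  expect_error(discontinuation_cost(44.50, 48.01, 1.2), "p_disc")
})

test_that("replacement-therapy cost is the class-mix weighted mean", {
  costs <- c(lama = 29.29, ics_laba = 31.79, lama_laba = 32.50,
             ics_lama_laba = 61.08)
  pure <- c(lama = 0, ics_laba = 0, lama_laba = 1, ics_lama_laba = 0)
  expect_equal(replacement_cost_30d(costs, pure), 32.50)
  uniform <- rep(0.25, 4)
  expect_equal(replacement_cost_30d(costs, uniform), 38.665)
  expect_error(replacement_cost_30d(costs, c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("pneumonia event cost weights ambulatory and inpatient management", {
  expect_equal(pneumonia_event_cost(100, 200, 0.5), 150)
  expect_equal(pneumonia_event_cost(100, 200, 0), 100)
  expect_equal(pneumonia_event_cost(100, 200, 1), 200)
})

test_that("trial utility AUC integrates the piecewise-linear EQ-5D trajectory", {
  expect_equal(trial_utility_auc(0.787, NULL), 0.787)
  expect_equal(trial_utility_auc(0.787, tibble::tibble(week = numeric(),
                                                       delta = numeric())),
               0.787)
  # flat at baseline to week 26, then linear rise to +0.1 at week 52:
  # area = (26 * 0.7 + 26 * (0.7 + 0.8) / 2) / 52
  traj <- tibble::tibble(week = c(26, 52), delta = c(0, 0.1))
  expect_equal(trial_utility_auc(0.7, traj), 0.725)
  expect_error(trial_utility_auc(0.7, tibble::tibble(week = c(30, 10),
                                                     delta = c(0, 0))),
               "sorted")
})

test_that("a single expected exacerbation leaves one event cost and one disutility", {
  arm <- make_arm(rate_moderate = 1)
  b <- toy_bundle(arms = list(A = arm))
  tp <- run_trial_phase(arm, b$costs, b$utilities, b$settings)
  expect_equal(tp$events[["moderate_exac"]], 1)
  expect_equal(tp$costs[["moderate_exac"]], 568.48)
  expect_equal(tp$qalys, 0.75 - 1 * 0.011)      # baseline utility minus loss
  expect_equal(tp$lys, 1)
  expect_equal(tp$surviving_fraction, 1)
})

test_that("with no events and full adherence year-1 cost is drug plus maintenance", {
  arm <- make_arm()
  b <- toy_bundle(arms = list(A = arm))
  tp <- run_trial_phase(arm, b$costs, b$utilities, b$settings)
  expect_equal(tp$qalys, 0.75)
  expect_equal(sum(tp$costs),
               annual_drug_cost(30) + 100)   # all mass in moderate, cost 100
  expect_equal(tp$costs[["replacement"]], 0)
  expect_true(validate_distribution(tp$start_distribution)$valid)
})

test_that("within-trial deaths accrue half-year credit and scale the Markov start", {
  arm <- make_arm(p_death = 0.2, rate_moderate = 0.5)
  b <- toy_bundle(arms = list(A = arm))
  tp <- run_trial_phase(arm, b$costs, b$utilities, b$settings)
  expect_equal(tp$lys, 1 - 0.5 * 0.2)
  expect_equal(tp$events[["moderate_exac"]], 0.5 * 0.9)
  expect_equal(sum(tp$start_distribution), 1, tolerance = 1e-12)
  expect_equal(tp$start_distribution[["death"]], 0.2)

  # scenario flag removes within-trial mortality entirely
  s <- modifyList(b$settings, list(include_trial_mortality = FALSE))
  tp2 <- run_trial_phase(arm, b$costs, b$utilities, s)
  expect_equal(tp2$surviving_fraction, 1)
  expect_equal(tp2$lys, 1)
})

test_that("identical arm inputs give identical trial-phase results", {
  a1 <- make_arm(label = "A", rate_moderate = 0.8, rate_severe = 0.1,
                 p_pneumonia = 0.07, p_death = 0.01, p_discontinuation = 0.2)
  a2 <- a1; a2$label <- "B"
  b <- toy_bundle(arms = list(A = a1, B = a2))
  t1 <- run_trial_phase(a1, b$costs, b$utilities, b$settings)
  t2 <- run_trial_phase(a2, b$costs, b$utilities, b$settings)
  expect_equal(t1$qalys, t2$qalys, tolerance = 1e-12)
  expect_equal(t1$costs, t2$costs, tolerance = 1e-12)
})

test_that("costs are linear in unit costs and QALYs linear in disutilities", {
  arm <- make_arm(rate_moderate = 0.8, rate_severe = 0.15, p_pneumonia = 0.06)
  b <- toy_bundle(arms = list(A = arm))
  tp0 <- run_trial_phase(arm, b$costs, b$utilities, b$settings)

  for (unit in c("moderate_exac", "severe_exac", "pneumonia")) {
    costs2 <- b$costs; costs2[[unit]] <- costs2[[unit]] * 2
    tp2 <- run_trial_phase(arm, costs2, b$utilities, b$settings)
    expect_equal(tp2$costs[[unit]], 2 * tp0$costs[[unit]], tolerance = 1e-12)
    other <- setdiff(names(tp0$costs), unit)
    expect_equal(tp2$costs[other], tp0$costs[other], tolerance = 1e-12)
  }

  u2 <- b$utilities
  u2$disutility[["severe_exac"]] <- u2$disutility[["severe_exac"]] + 0.01
  tp3 <- run_trial_phase(arm, b$costs, u2, b$settings)
  expect_equal(tp0$qalys - tp3$qalys, 0.01 * tp0$events[["severe_exac"]],
               tolerance = 1e-12)
})
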