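psa_base <- function() {
  a1 <- make_arm(label = "A", drug_cost_30d = 44.50, rate_moderate = 0.78,
                 rate_severe = 0.13, p_pneumonia = 0.08, p_death = 0.012,
                 p_discontinuation = 0.18,
                 trial_end = c(moderate.no_recent = 0.25, moderate.recent = 0.2,
                               severe.no_recent = 0.2, severe.recent = 0.15,
                               very_severe.no_recent = 0.12,
                               very_severe.recent = 0.08))
  a2 <- a1
  a2$label <- "B"; a2$drug_cost_30d <- 22
  a2$rate_moderate <- 0.92; a2$rate_severe <- 0.15
  a2$trial_end <- c(moderate.no_recent = 0.2, moderate.recent = 0.18,
                    severe.no_recent = 0.21, severe.recent = 0.17,
                    very_severe.no_recent = 0.14, very_severe.recent = 0.10)
  b <- toy_bundle(q = 0.03, progression = 0.1, p_exac = 0.35, horizon = 15,
                  arms = list(A = a1, B = a2))
  # graded risks (rather than the flat toy default) so that correlated PSA
  # draws respect the severity/history ordering with high probability
  b$exacerbation$p_moderate <- c(0.40, 0.54, 0.50, 0.675, 0.625, 0.84375)
  b$exacerbation$p_severe <- c(0.10, 0.135, 0.125, 0.16875, 0.15625, 0.2109375)
  copdcea::validate_parameters(b)
  b
}

test_that("the Cholesky factor reproduces its covariance and rejects non-PSD input", {
  expect_equal(cholesky_factor(diag(3)), diag(3))
  expect_equal(cholesky_factor(diag(c(9, 16))), diag(c(3, 4)))

  m <- matrix(c(4, 2, 2, 3), 2)
  L <- cholesky_factor(m)
  expect_equal(L, matrix(c(2, 1, 0, sqrt(2)), 2), tolerance = 1e-12)
  expect_equal(L[2, 2], 1.41421356, tolerance = 1e-8)
  expect_true(all(L[upper.tri(L)] == 0))

  set.seed(7)
  A <- matrix(rnorm(25), 5); S <- A %*% t(A)
  expect_equal(cholesky_factor(S) %*% t(cholesky_factor(S)), S,
               tolerance = 1e-10)

  # positive SEMI-definite (rank deficient) is accepted
  v <- c(1, 2, 3); S1 <- outer(v, v)
  L1 <- cholesky_factor(S1)
  expect_equal(L1 %*% t(L1), S1, tolerance = 1e-10)

  bad <- matrix(c(1, 2, 2, 1), 2)   # indefinite
  expect_error(cholesky_factor(bad), "leading minor of order 2")
  expect_error(cholesky_factor(matrix(c(1, 0.5, 0, 1), 2)), "symmetric")
})

test_that("empirical covariance of correlated draws matches the target", {
  k <- 6
  cov <- (diag(0.7, k) + 0.3) * 0.04     # exchangeable, sd 0.2
  L <- cholesky_factor(cov)
  set.seed(123)
  Z <- matrix(rnorm(100000 * k), ncol = k)
  X <- Z %*% t(L)
  emp <- stats::cov(X)
  rel_frob <- norm(emp - cov, "F") / norm(cov, "F")
  expect_lt(rel_frob, 0.05)
})

test_that("a PSA draw is reproducible and a degenerate spec returns the base case", {
  b <- psa_base()
  spec <- psa_spec(b, n_draws = 10, seed = 99)
  d1 <- sample_draw(b, spec, 3)
  d2 <- sample_draw(b, spec, 3)
  expect_equal(d1, d2, tolerance = 1e-15)
  d3 <- sample_draw(b, spec, 4)
  expect_false(isTRUE(all.equal(d1$utilities$state, d3$utilities$state)))

  degenerate <- psa_spec(b, n_draws = 5, seed = 1, noise_scale = 0)
  dd <- sample_draw(b, degenerate, 1)
  expect_equal(dd$utilities$state, b$utilities$state, tolerance = 1e-15)
  expect_equal(dd$exacerbation, b$exacerbation, tolerance = 1e-15)
  expect_equal(dd$arms$A$trial_end, b$arms$A$trial_end, tolerance = 1e-15)

  psa <- run_psa(b, degenerate, intervention = "A")
  expect_equal(unique(psa$draws$delta_cost), psa$base$delta_cost,
               tolerance = 1e-12)
  expect_equal(unique(psa$draws$delta_qaly), psa$base$delta_qaly,
               tolerance = 1e-12)
})

test_that("beta hyperparameters from moments recover the intended mean", {
  b <- psa_base()
  spec <- psa_spec(b, n_draws = 1, seed = 5)
  row <- spec$params[spec$params$id == "utility.moderate", ]
  set.seed(11)
  draws <- stats::rbeta(50000, row$par1, row$par2)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - row$mean), 3 * se)
  expect_equal(row$par1 / (row$par1 + row$par2), row$mean, tolerance = 1e-9)
})

test_that("PSA mean deltas recover base-case deltas when the model is linear in draws", {
  b <- psa_base()
  # transition/exacerbation block, trial-end resampling and the mortality
  # relative risks (which enter survival through a power, hence nonlinearly)
  # are frozen so every sampled parameter enters the accounting linearly
  spec <- psa_spec(b, n_draws = 400, seed = 17, coef_sd_logit = 0)
  spec$dirichlet$effective_n <- 0
  rr_rows <- grepl("^mortality_rr", spec$params$id)
  spec$params$par1[rr_rows] <- NA
  spec$params$sd[rr_rows] <- 0
  psa <- run_psa(b, spec, intervention = "A")
  for (col in c("delta_qaly", "delta_cost")) {
    mc_se <- stats::sd(psa$draws[[col]]) / sqrt(nrow(psa$draws))
    expect_lt(abs(mean(psa$draws[[col]]) - psa$base[[col]]), 3 * mc_se)
  }
})

test_that("the acceptability curve is the net-monetary-benefit exceedance", {
  single <- tibble::tibble(delta_cost = 1129, delta_qaly = 0.275)
  expect_equal(ceac(single, 20000)$p_cost_effective, 1)    # NMB = 4371 > 0
  expect_equal(ceac(single, 4000)$p_cost_effective, 0)     # NMB = -29 < 0
  # the step sits exactly at the base-case ICER
  icer <- 1129 / 0.275
  expect_equal(ceac(single, icer + 1e-6)$p_cost_effective, 1)
  expect_equal(ceac(single, icer - 1e-6)$p_cost_effective, 0)

  dominant <- tibble::tibble(delta_cost = c(-10, -20), delta_qaly = c(0.1, 0.2))
  cc <- ceac(dominant, seq(0, 50000, 10000))
  expect_true(all(cc$p_cost_effective == 1))

  set.seed(3)
  pos <- tibble::tibble(delta_cost = rnorm(500, 1000, 400),
                        delta_qaly = runif(500, 0.01, 0.5))
  curve <- ceac(pos, seq(0, 50000, 1000))$p_cost_effective
  expect_true(all(diff(curve) >= 0))          # monotone when all dQALY > 0
  expect_equal(ceac(pos, 0)$p_cost_effective, mean(pos$delta_cost < 0))
  expect_error(ceac(pos, numeric(0)), "non-empty")
})

test_that("one-way sensitivity results are ordered, directional and stable", {
  b <- psa_base()
  tor <- suppressWarnings(run_owsa(b, intervention = "A", comparator = "B"))
  expect_s3_class(tor, "cea_tornado")
  spans <- tor$span[!is.na(tor$span)]
  expect_true(all(diff(spans) <= 1e-12))      # sorted descending by span

  # +20% on the intervention drug cost strictly raises the ICER
  base_icer <- run_cea(b, "A", "B")$comparisons$icer_qaly
  up <- copdcea:::apply_perturbation(b, "drug_cost_A", 1.2)
  up_icer <- run_cea(up, "A", "B")$comparisons$icer_qaly
  expect_gt(up_icer, base_icer)
  row <- tor[tor$parameter == "drug_cost_A", ]
  expect_lt(row$icer_low, row$icer_base)
  expect_gt(row$icer_high, row$icer_base)

  # a parameter with no influence on either arm leaves the ICER unchanged:
  # drug cost of an arm outside the comparison
  a3 <- b$arms$A; a3$label <- "C"
  b3 <- b; b3$arms$C <- a3
  spec3 <- owsa_default_spec(names(b3$arms))
  tor3 <- suppressWarnings(run_owsa(b3, spec3, intervention = "A", comparator = "B"))
  row3 <- tor3[tor3$parameter == "drug_cost_C", ]
  expect_equal(row3$icer_low, row3$icer_base, tolerance = 1e-12)
  expect_equal(row3$icer_high, row3$icer_base, tolerance = 1e-12)
  expect_equal(row3$span, 0, tolerance = 1e-12)

  # spec order does not affect the (deterministically sorted) output
  spec_rev <- owsa_default_spec(names(b$arms))
  tor_rev <- suppressWarnings(
    run_owsa(b, spec_rev[rev(seq_len(nrow(spec_rev))), ],
             intervention = "A", comparator = "B"))
  expect_equal(tor_rev$parameter, tor$parameter)

  # perturbations that would break an invariant are clamped with a warning
  expect_warning(copdcea:::apply_perturbation(b, "utility_severe", 1.2),
                 "clamped")
})
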