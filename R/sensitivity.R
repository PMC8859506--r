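#' Default one-way sensitivity analysis specification
#'
#' Parameters perturbed one at a time, both directions, holding all else at
#' base case: the moderate and very-severe state utilities, all
#' exacerbation rates/risks jointly, the mortality relative risks, each
#' arm's drug acquisition cost, and the maintenance costs.
#'
#' @param arms Arm labels (a drug-cost parameter is emitted per arm).
#' @param perturbation Symmetric relative perturbation (default 0.2 for
#'   +/-20%).
#' @return A tibble with columns `parameter`, `low`, `high` (multipliers).
#' @export
owsa_default_spec <- function(arms, perturbation = 0.2) {
  ids <- c("utility_moderate", "utility_very_severe", "exacerbation_rates",
           "mortality_rr", paste0("drug_cost_", arms), "maintenance_costs")
  tibble::tibble(parameter = ids, low = 1 - perturbation, high = 1 + perturbation)
}

# apply a named multiplicative perturbation to a bundle; clamps that keep
# the bundle inside its invariants are reported with a warning
apply_perturbation <- function(params, parameter, factor) {
  clamp_warn <- function(value, upper, what) {
    if (any(value > upper)) {
      warning("perturbation of '", what, "' clamped to keep invariants",
              call. = FALSE)
      value <- pmin(value, upper)
    }
    value
  }
  u <- params$utilities$state
  if (parameter == "utility_moderate") {
    params$utilities$state[["moderate"]] <-
      clamp_warn(u[["moderate"]] * factor, 1, parameter)
  } else if (parameter == "utility_severe") {
    params$utilities$state[["severe"]] <-
      clamp_warn(u[["severe"]] * factor, u[["moderate"]] - 1e-9, parameter)
  } else if (parameter == "utility_very_severe") {
    params$utilities$state[["very_severe"]] <-
      clamp_warn(u[["very_severe"]] * factor, u[["severe"]] - 1e-9, parameter)
  } else if (parameter == "exacerbation_rates") {
    params$exacerbation$p_moderate <-
      clamp_warn(params$exacerbation$p_moderate * factor, 1, parameter)
    params$exacerbation$p_severe <-
      clamp_warn(params$exacerbation$p_severe * factor, 1, parameter)
    for (a in names(params$arms)) {
      params$arms[[a]]$rate_moderate <- params$arms[[a]]$rate_moderate * factor
      params$arms[[a]]$rate_severe <- params$arms[[a]]$rate_severe * factor
    }
  } else if (parameter == "mortality_rr") {
    params$mortality$rr <- pmax(1, params$mortality$rr * factor)
  } else if (parameter == "maintenance_costs") {
    params$costs$maintenance <- params$costs$maintenance * factor
  } else if (grepl("^drug_cost_", parameter)) {
    arm <- sub("^drug_cost_", "", parameter)
    if (!arm %in% names(params$arms)) {
      stop("unknown OWSA parameter '", parameter, "'", call. = FALSE)
    }
    params$arms[[arm]]$drug_cost_30d <- params$arms[[arm]]$drug_cost_30d * factor
  } else {
    stop("unknown OWSA parameter '", parameter, "'", call. = FALSE)
  }
  params
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full model with each parameter perturbed to its low and high
#' bound in turn, and reports both resulting ICERs per QALY for one
#' pairwise comparison, sorted by ICER span, descending.
#'
#' @param base A `"cea_parameters"` bundle.
#' @param spec Perturbation spec (default [owsa_default_spec()]).
#' @param intervention,comparator Arm labels of the comparison.
#' @return A tibble of class `"cea_tornado"`: `parameter`, `icer_low`,
#'   `icer_high`, `icer_base`, `span`. Dominant outcomes enter as `NA` with
#'   the verdict in `verdict_low`/`verdict_high`.
#' @export
run_owsa <- function(base, spec = NULL,
                     intervention = names(base$arms)[1],
                     comparator = names(base$arms)[2]) {
  if (is.null(spec)) spec <- owsa_default_spec(names(base$arms))
  icer_of <- function(params) {
    res <- run_cea(params, intervention, comparator)
    cmp <- res$comparisons[1, ]
    list(icer = cmp$icer_qaly, verdict = cmp$verdict)
  }
  base_icer <- icer_of(base)
  rows <- purrr::pmap(spec, function(parameter, low, high, ...) {
    lo <- icer_of(apply_perturbation(base, parameter, low))
    hi <- icer_of(apply_perturbation(base, parameter, high))
    tibble::tibble(
      parameter = parameter,
      icer_low = lo$icer, icer_high = hi$icer,
      verdict_low = lo$verdict, verdict_high = hi$verdict,
      icer_base = base_icer$icer,
      span = abs((hi$icer %||% NA_real_) - (lo$icer %||% NA_real_))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(!is.na(span)), dplyr::desc(span),
                        parameter)
  class(out) <- c("cea_tornado", class(out))
  attr(out, "comparison") <- c(intervention, comparator)
  out
}

#' Lower-triangular Cholesky factor
#'
#' Decomposes a symmetric positive semi-definite covariance matrix as
#' `L %*% t(L)` with `L` lower triangular. Semi-definite inputs are
#' handled by zeroing the column at a (numerically) zero pivot. Used to
#' impose the estimated correlation structure on risk-equation coefficient
#' draws in the probabilistic sensitivity analysis.
#'
#' @param cov Symmetric positive semi-definite matrix.
#' @param tol Relative tolerance for declaring a pivot negative.
#' @return Lower-triangular matrix `L` with `L %*% t(L)` equal to `cov`.
#' @export
cholesky_factor <- function(cov, tol = 1e-10) {
  cov <- as.matrix(cov)
  n <- nrow(cov)
  if (n != ncol(cov) || any(abs(cov - t(cov)) > tol * max(1, max(abs(cov))))) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  L <- matrix(0, n, n, dimnames = dimnames(cov))
  scale <- max(1, max(abs(diag(cov))))
  for (j in seq_len(n)) {
    pivot <- cov[j, j] - sum(L[j, seq_len(j - 1)]^2)
    if (pivot < -tol * scale) {
      stop("matrix is not positive semi-definite: leading minor of order ",
           j, " is negative", call. = FALSE)
    }
    pivot <- max(pivot, 0)
    L[j, j] <- sqrt(pivot)
    if (j < n) {
      for (i in (j + 1):n) {
        s <- cov[i, j] - sum(L[i, seq_len(j - 1)] * L[j, seq_len(j - 1)])
        L[i, j] <- if (L[j, j] > 0) s / L[j, j] else 0
      }
    }
  }
  L
}

# ---- PSA specification -----------------------------------------------------

# method-of-moments hyperparameters
beta_from_moments <- function(mean, sd) {
  if (sd <= 0) return(c(shape1 = NA, shape2 = NA))
  v <- sd^2
  v <- min(v, mean * (1 - mean) * 0.999)  # keep inside the feasible region
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

gamma_from_moments <- function(mean, sd) {
  shape <- (mean / sd)^2
  c(shape = shape, rate = shape / mean)
}

lnorm_from_moments <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

ci_to_sd <- function(lower, upper) (upper - lower) / (2 * stats::qnorm(0.975))

#' Build a probabilistic sensitivity analysis specification
#'
#' Assigns a sampling distribution to every uncertain parameter: beta for
#' probabilities and utilities (hyperparameters from published 95%
#' confidence intervals where available, otherwise an effective trial-arm
#' sample size), gamma for costs (coefficient of variation `cost_cv`),
#' log-normal for mortality relative risks, gamma for trial exacerbation
#' rates, and Dirichlet (via an effective sample size) for trial-end state
#' distributions. Transition and per-state exacerbation probabilities form
#' a correlated block sampled on the logit scale with an exchangeable
#' correlation, reflecting their joint estimation by the underlying risk
#' equations; the block covariance is factored with [cholesky_factor()].
#' Drug acquisition costs are list prices and are not sampled.
#'
#' @param bundle A `"cea_parameters"` bundle.
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Master seed; per-draw substreams are derived from it.
#' @param cost_cv Coefficient of variation for cost parameters.
#' @param rr_cv Coefficient of variation for mortality relative risks.
#' @param rate_cv Coefficient of variation for trial exacerbation rates.
#' @param effective_n Effective per-arm sample size for trial proportions
#'   and trial-end distributions.
#' @param coef_sd_logit Marginal standard deviation of the correlated
#'   logit-scale probability block.
#' @param coef_correlation Exchangeable correlation of the block.
#' @param noise_scale Global multiplier on every spread (0 gives a
#'   degenerate spec whose draws all equal the base case).
#' @return A list of class `"cea_psa_spec"` with elements `params` (tibble:
#'   id, family, mean, par1, par2), `coef_block` (ids, mean, cov, and its
#'   Cholesky factor), `dirichlet` (per-arm effective counts), `n_draws`,
#'   `seed`.
#' @export
psa_spec <- function(bundle, n_draws = 10000, seed = 20180101,
                     cost_cv = 0.2, rr_cv = 0.2, rate_cv = 0.1,
                     effective_n = 4000, coef_sd_logit = 0.1,
                     coef_correlation = 0.3, noise_scale = 1) {
  rows <- list()
  add <- function(id, family, mean, sd) {
    sd <- sd * noise_scale
    pars <- if (sd <= 0 || mean == 0) {
      c(NA_real_, NA_real_)
    } else {
      switch(family,
             beta = beta_from_moments(mean, sd),
             gamma = gamma_from_moments(mean, sd),
             lnorm = lnorm_from_moments(mean, sd))
    }
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = id, family = family, mean = mean, sd = sd,
      par1 = unname(pars[1]), par2 = unname(pars[2]))
  }

  u <- bundle$utilities
  for (s in cea_severities()) {
    ci <- u$state_ci
    sd <- if (!is.null(ci) && s %in% ci$severity) {
      ci_to_sd(ci$lower[ci$severity == s], ci$upper[ci$severity == s])
    } else {
      0.05 * u$state[[s]]
    }
    add(paste0("utility.", s), "beta", u$state[[s]], sd)
  }
  for (ev in names(u$disutility)) {
    ci <- u$disutility_ci
    sd <- if (!is.null(ci) && ev %in% ci$event) {
      ci_to_sd(ci$lower[ci$event == ev], ci$upper[ci$event == ev])
    } else {
      0.25 * u$disutility[[ev]]
    }
    add(paste0("disutility.", ev), "beta", u$disutility[[ev]], sd)
  }
  for (s in cea_severities()) {
    add(paste0("cost.maintenance.", s), "gamma",
        bundle$costs$maintenance[[s]], cost_cv * bundle$costs$maintenance[[s]])
  }
  for (ev in c("moderate_exac", "severe_exac", "pneumonia")) {
    add(paste0("cost.", ev), "gamma", bundle$costs[[ev]],
        cost_cv * bundle$costs[[ev]])
  }
  for (s in cea_severities()) {
    add(paste0("mortality_rr.", s), "lnorm", bundle$mortality$rr[[s]],
        rr_cv * bundle$mortality$rr[[s]])
  }
  for (a in names(bundle$arms)) {
    arm <- bundle$arms[[a]]
    add(paste0("arm.", a, ".rate_moderate"), "gamma", arm$rate_moderate,
        rate_cv * arm$rate_moderate)
    add(paste0("arm.", a, ".rate_severe"), "gamma", arm$rate_severe,
        rate_cv * arm$rate_severe)
    for (p in c("p_pneumonia", "p_death", "p_discontinuation")) {
      add(paste0("arm.", a, ".", p), "beta", arm[[p]],
          sqrt(arm[[p]] * (1 - arm[[p]]) / effective_n))
    }
  }

  ex <- bundle$exacerbation
  key <- paste(ex$severity, ex$stratum, sep = ".")
  tr <- bundle$transitions
  coef_ids <- c(paste0("exac.p_moderate.", key), paste0("exac.p_severe.", key),
                "trans.moderate.p_to_severe", "trans.severe.p_to_very_severe",
                "trans.moderate.p_to_very_severe")
  coef_mean_p <- c(ex$p_moderate, ex$p_severe,
                   tr$p_to_severe[tr$severity == "moderate"],
                   tr$p_to_very_severe[tr$severity == "severe"],
                   tr$p_to_very_severe[tr$severity == "moderate"])
  keep <- coef_mean_p > 0 & coef_mean_p < 1
  coef_ids <- coef_ids[keep]
  coef_mean <- stats::qlogis(coef_mean_p[keep])
  k <- length(coef_ids)
  sdl <- coef_sd_logit * noise_scale
  cov <- (diag(1 - coef_correlation, k) + coef_correlation) * sdl^2
  dimnames(cov) <- list(coef_ids, coef_ids)

  structure(
    list(
      params = dplyr::bind_rows(rows),
      coef_block = list(ids = coef_ids, mean = coef_mean, cov = cov,
                        chol = if (sdl > 0) cholesky_factor(cov) else
                          matrix(0, k, k, dimnames = dimnames(cov))),
      dirichlet = list(effective_n = effective_n * noise_scale),
      n_draws = as.integer(n_draws),
      seed = as.integer(seed)
    ),
    class = "cea_psa_spec"
  )
}

# deterministic per-draw substream seed (kept inside 32-bit integer range)
substream_seed <- function(master_seed, draw_index, attempt = 0L) {
  as.integer((as.double(master_seed) * 48271 + draw_index * 69621 +
                attempt * 16807) %% 2147483647)
}

#' Draw one parameter bundle from a PSA specification
#'
#' Reproducible given `(spec$seed, draw_index)`: each draw uses its own
#' random substream so draws are order-independent. Marginal parameters are
#' drawn from their assigned families; the transition/exacerbation block is
#' drawn as `mean + L z` on the logit scale with `z` standard normal and
#' `L` the Cholesky factor of the block covariance. A draw violating a
#' structural invariant (e.g. risk ordering) is rejected and re-drawn, up
#' to 100 attempts.
#'
#' @param base The base-case `"cea_parameters"` bundle.
#' @param spec A `"cea_psa_spec"`.
#' @param draw_index 1-based draw number.
#' @return A valid `"cea_parameters"` bundle.
#' @export
sample_draw <- function(base, spec, draw_index) {
  for (attempt in 0:99) {
    bundle <- with_seed(substream_seed(spec$seed, draw_index, attempt),
                        draw_once(base, spec))
    ok <- tryCatch({ validate_parameters(bundle); TRUE },
                   error = function(e) FALSE)
    if (ok) return(bundle)
  }
  stop("draw ", draw_index, " failed structural validation 100 times; ",
       "PSA spec spreads are too wide for the parameter ordering constraints",
       call. = FALSE)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

draw_marginal <- function(family, mean, par1, par2) {
  if (is.na(par1)) return(mean)
  switch(family,
         beta = stats::rbeta(1, par1, par2),
         gamma = stats::rgamma(1, shape = par1, rate = par2),
         lnorm = stats::rlnorm(1, meanlog = par1, sdlog = par2))
}

draw_once <- function(base, spec) {
  p <- spec$params
  values <- stats::setNames(
    purrr::pmap_dbl(p[c("family", "mean", "par1", "par2")], draw_marginal),
    p$id)
  b <- base

  for (s in cea_severities()) {
    b$utilities$state[[s]] <- values[[paste0("utility.", s)]]
    b$costs$maintenance[[s]] <- values[[paste0("cost.maintenance.", s)]]
    b$mortality$rr[[s]] <- values[[paste0("mortality_rr.", s)]]
  }
  for (ev in names(b$utilities$disutility)) {
    b$utilities$disutility[[ev]] <- values[[paste0("disutility.", ev)]]
  }
  for (ev in c("moderate_exac", "severe_exac", "pneumonia")) {
    b$costs[[ev]] <- values[[paste0("cost.", ev)]]
  }
  for (a in names(b$arms)) {
    for (f in c("rate_moderate", "rate_severe", "p_pneumonia", "p_death",
                "p_discontinuation")) {
      b$arms[[a]][[f]] <- values[[paste0("arm.", a, ".", f)]]
    }
    n_eff <- spec$dirichlet$effective_n
    if (n_eff > 0) {
      alpha <- pmax(base$arms[[a]]$trial_end * n_eff, 1e-6)
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      b$arms[[a]]$trial_end <- stats::setNames(g / sum(g), names(alpha))
    }
  }

  cb <- spec$coef_block
  if (length(cb$ids)) {
    z <- stats::rnorm(length(cb$ids))
    logit_p <- cb$mean + as.vector(cb$chol %*% z)
    pv <- stats::setNames(stats::plogis(logit_p), cb$ids)
    ex <- b$exacerbation
    key <- paste(ex$severity, ex$stratum, sep = ".")
    for (i in seq_along(key)) {
      idm <- paste0("exac.p_moderate.", key[i])
      ids <- paste0("exac.p_severe.", key[i])
      if (idm %in% cb$ids) ex$p_moderate[i] <- pv[[idm]]
      if (ids %in% cb$ids) ex$p_severe[i] <- pv[[ids]]
    }
    b$exacerbation <- ex
    tr <- b$transitions
    if ("trans.moderate.p_to_severe" %in% cb$ids) {
      tr$p_to_severe[tr$severity == "moderate"] <- pv[["trans.moderate.p_to_severe"]]
    }
    if ("trans.severe.p_to_very_severe" %in% cb$ids) {
      tr$p_to_very_severe[tr$severity == "severe"] <- pv[["trans.severe.p_to_very_severe"]]
    }
    if ("trans.moderate.p_to_very_severe" %in% cb$ids) {
      tr$p_to_very_severe[tr$severity == "moderate"] <- pv[["trans.moderate.p_to_very_severe"]]
    }
    b$transitions <- tr
  }
  b
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the full model on each of `n_draws` parameter bundles sampled by
#' [sample_draw()] and records the incremental cost and effect of every
#' comparison per draw.
#'
#' @param base A `"cea_parameters"` bundle.
#' @param spec A `"cea_psa_spec"` (default: [psa_spec()] of `base`).
#' @param intervention,comparators Arm labels (defaults as in [run_cea()]).
#' @param n_draws Optional override of `spec$n_draws`.
#' @return A list of class `"cea_psa"`: `draws` (tibble: draw,
#'   intervention, comparator, delta_cost, delta_qaly, delta_ly), `base`
#'   (the base-case comparison tibble), `spec`, `wtp_grid`.
#' @export
run_psa <- function(base, spec = psa_spec(base),
                    intervention = names(base$arms)[1],
                    comparators = setdiff(names(base$arms), intervention),
                    n_draws = NULL) {
  n <- n_draws %||% spec$n_draws
  base_res <- run_cea(base, intervention, comparators)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    bundle <- sample_draw(base, spec, i)
    res <- run_cea(bundle, intervention, comparators)
    rows[[i]] <- dplyr::mutate(
      res$comparisons[c("intervention", "comparator", "delta_cost",
                        "delta_qaly", "delta_ly")],
      draw = i, .before = 1)
  }
  structure(
    list(draws = dplyr::bind_rows(rows),
         base = base_res$comparisons,
         spec = spec,
         wtp_grid = base$settings$wtp_grid),
    class = "cea_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of draws whose net
#' monetary benefit `wtp * delta_qaly - delta_cost` is positive.
#'
#' @param pairs A data frame of draws with columns `delta_cost` and
#'   `delta_qaly` (and optionally `intervention`/`comparator`, by which the
#'   curve is grouped).
#' @param wtp_grid Willingness-to-pay grid (GBP per QALY); must be
#'   non-empty.
#' @return A tibble: one row per (comparison,) wtp value with
#'   `p_cost_effective` in `[0, 1]`.
#' @export
ceac <- function(pairs, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0L) stop("wtp_grid must be non-empty", call. = FALSE)
  if (nrow(pairs) == 0L) stop("at least one draw is required", call. = FALSE)
  if (!all(c("intervention", "comparator") %in% names(pairs))) {
    pairs$intervention <- "intervention"
    pairs$comparator <- "comparator"
  }
  dplyr::bind_rows(lapply(wtp_grid, function(l) {
    dplyr::summarise(
      dplyr::group_by(pairs, .data$intervention, .data$comparator),
      wtp = l,
      p_cost_effective = mean(l * .data$delta_qaly - .data$delta_cost > 0),
      .groups = "drop")
  }))
}

#' @export
print.cea_psa <- function(x, ...) {
  n <- length(unique(x$draws$draw))
  cat("<cea_psa>", n, "draws,",
      nrow(x$base), "comparisons\n")
  cc <- ceac(x$draws, 20000)
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  P(cost-effective at 20000/QALY), %s vs %s: %.3f\n",
                cc$intervention[i], cc$comparator[i], cc$p_cost_effective[i]))
  }
  invisible(x)
}
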