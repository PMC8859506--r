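#' Health states of the COPD cohort model
#'
#' The Markov phase tracks a cohort over six living health states -- three
#' FEV1-defined severity grades (moderate: 50--<80% predicted, severe:
#' 30--<50%, very severe: <30%) each split by recent exacerbation history
#' (an exacerbation within the previous annual cycle) -- plus absorbing
#' death.
#'
#' @return Character vector of the seven state labels, living states first,
#'   `"death"` last.
#' @export
#' @examples
#' cea_states()
cea_states <- function() STATES7

#' @rdname cea_states
#' @export
cea_living_states <- function() LIVING6

#' @rdname cea_states
#' @export
cea_severities <- function() SEVERITIES3

SEVERITIES3 <- c("moderate", "severe", "very_severe")
LIVING6 <- paste(rep(SEVERITIES3, each = 2L),
                 rep(c("no_recent", "recent"), 3L), sep = ".")
STATES7 <- c(LIVING6, "death")
SEV_IDX6 <- rep(1:3, each = 2L)

#' FEV1 percent-predicted bands defining the severity grades
#'
#' @return A tibble with one row per severity grade and the half-open
#'   FEV1 %-predicted interval `[lower, upper)` that defines it.
#' @export
severity_bands <- function() {
  tibble::tibble(
    severity = cea_severities(),
    fev1_lower = c(50, 30, 0),
    fev1_upper = c(80, 50, 30)
  )
}

# severity label of each living state, in cea_living_states() order
state_severity <- function(states = cea_living_states()) {
  sub("\\.(no_recent|recent)$", "", states)
}

# exacerbation-history stratum of each living state
state_stratum <- function(states = cea_living_states()) {
  sub("^.*\\.", "", states)
}

#' Validate a cohort occupancy distribution
#'
#' A valid cohort distribution assigns a non-negative occupancy fraction to
#' each of the seven health states (death included) and sums to 1 within
#' `tol`.
#'
#' @param d Numeric vector of occupancy fractions. If named, names must be
#'   the state labels of [cea_states()]; an unnamed vector of length 7 is
#'   taken in [cea_states()] order.
#' @param tol Absolute tolerance on the total mass (default `1e-9`).
#' @return A list with class `"cea_distribution_check"`: `valid` (logical),
#'   `total`, `deficit` (`1 - total`), and `negative_states` (labels of any
#'   states with negative occupancy).
#' @export
#' @examples
#' d <- c(rep(0, 6), 1)            # everyone dead: still a valid distribution
#' validate_distribution(d)$valid
validate_distribution <- function(d, tol = 1e-9) {
  states <- cea_states()
  if (is.null(names(d))) {
    stopifnot(length(d) == length(states))
    names(d) <- states
  } else {
    stopifnot(setequal(names(d), states))
    d <- d[states]
  }
  total <- sum(d)
  neg <- names(d)[d < -tol]
  out <- list(
    valid = length(neg) == 0L && abs(total - 1) <= tol,
    total = total,
    deficit = 1 - total,
    negative_states = neg
  )
  class(out) <- "cea_distribution_check"
  out
}

#' @export
print.cea_distribution_check <- function(x, ...) {
  cat("cohort distribution check:", if (x$valid) "valid" else "INVALID", "\n")
  cat("  total mass:", format(x$total, digits = 12), "\n")
  if (length(x$negative_states)) {
    cat("  negative occupancy in:", paste(x$negative_states, collapse = ", "), "\n")
  }
  invisible(x)
}

# internal: coerce a living-state distribution (length 6) into the 7-state
# layout with a given death mass
full_distribution <- function(living, death = 0) {
  states <- cea_states()
  d <- stats::setNames(numeric(7L), states)
  if (is.null(names(living))) names(living) <- cea_living_states()
  d[names(living)] <- living
  d["death"] <- death
  d
}
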