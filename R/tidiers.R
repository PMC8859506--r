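#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-arm totals of a cost-effectiveness run
#'
#' @param x A `"cea_result"`.
#' @param discounted Report discounted (default) or undiscounted totals.
#' @param ... Unused.
#' @return A tibble: one row per arm and quantity (`lys`, `qalys`, cost
#'   categories, `total_cost`, expected event counts) with its `value`.
#' @export
tidy.cea_result <- function(x, discounted = TRUE, ...) {
  which <- if (discounted) "discounted" else "undiscounted"
  dplyr::bind_rows(purrr::imap(x$arms, function(e, nm) {
    v <- c(e[[which]], e$events)
    tibble::tibble(arm = nm, quantity = names(v), value = unname(v))
  }))
}

#' One-row-per-comparison summary of a cost-effectiveness run
#'
#' @param x A `"cea_result"`.
#' @param ... Unused.
#' @return The comparisons tibble: deltas, ICERs and verdicts.
#' @export
glance.cea_result <- function(x, ...) x$comparisons

#' Tidy the per-draw incremental cloud of a PSA
#'
#' @param x A `"cea_psa"`.
#' @param ... Unused.
#' @return The draws tibble (draw, comparison, `delta_cost`, `delta_qaly`,
#'   `delta_ly`).
#' @export
tidy.cea_psa <- function(x, ...) x$draws

#' Per-comparison PSA summary
#'
#' @param x A `"cea_psa"`.
#' @param wtp Willingness-to-pay threshold for the acceptability
#'   probability (GBP/QALY).
#' @param ... Unused.
#' @return A tibble per comparison: mean deltas over draws, the base-case
#'   deltas, and `p_cost_effective` at `wtp`.
#' @export
glance.cea_psa <- function(x, wtp = 20000, ...) {
  means <- dplyr::summarise(
    dplyr::group_by(x$draws, .data$intervention, .data$comparator),
    mean_delta_cost = mean(.data$delta_cost),
    mean_delta_qaly = mean(.data$delta_qaly),
    mean_delta_ly = mean(.data$delta_ly),
    .groups = "drop")
  cc <- ceac(x$draws, wtp)
  base <- x$base[c("intervention", "comparator", "delta_cost", "delta_qaly")]
  names(base)[3:4] <- c("base_delta_cost", "base_delta_qaly")
  dplyr::left_join(dplyr::left_join(means, base,
                                    by = c("intervention", "comparator")),
                   cc[c("intervention", "comparator", "p_cost_effective")],
                   by = c("intervention", "comparator"))
}

#' @export
tidy.cea_tornado <- function(x, ...) {
  tibble::as_tibble(x)[c("parameter", "icer_low", "icer_high",
                         "icer_base", "span")]
}
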