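#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars from the low-bound to the high-bound ICER per
#' parameter, ordered by span, with the base-case ICER as a vertical
#' reference line.
#'
#' @param object A `"cea_tornado"` from [run_owsa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cea_tornado <- function(object, ...) {
  df <- tidy.cea_tornado(object)
  df <- df[!is.na(df$span), ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = df$icer_base[1], linetype = 2) +
    ggplot2::labs(x = "ICER (GBP per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter of PSA draws
#'
#' @param object A `"cea_psa"` from [run_psa()].
#' @param wtp Willingness-to-pay threshold drawn as a reference line
#'   (GBP/QALY).
#' @param ... Unused.
#' @return A ggplot object: one point per draw on the incremental
#'   cost-effectiveness plane, faceted by comparison.
#' @export
autoplot.cea_psa <- function(object, wtp = 20000, ...) {
  df <- object$draws
  df$comparison <- paste(df$intervention, "vs", df$comparator)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "PSA incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param psa A `"cea_psa"` (or a draws data frame accepted by [ceac()]).
#' @param wtp_grid Willingness-to-pay grid (GBP/QALY).
#' @return A ggplot object: probability cost-effective against
#'   willingness-to-pay, one curve per comparison.
#' @export
plot_ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  draws <- if (inherits(psa, "cea_psa")) psa$draws else psa
  cc <- ceac(draws, wtp_grid)
  cc$comparison <- paste(cc$intervention, "vs", cc$comparator)
  ggplot2::ggplot(cc, ggplot2::aes(.data$wtp, .data$p_cost_effective,
                                   colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cohort occupancy over the Markov phase
#'
#' @param object A `"cea_markov_trace"` from [run_markov()].
#' @param ... Unused.
#' @return A ggplot object: stacked state occupancy per cycle.
#' @export
autoplot.cea_markov_trace <- function(object, ...) {
  occ_cols <- paste0("occ_", cea_states())
  df <- tidyr::pivot_longer(tibble::as_tibble(object)[c("cycle", occ_cols)],
                            -"cycle", names_to = "state",
                            values_to = "occupancy",
                            names_prefix = "occ_")
  df$state <- factor(df$state, levels = cea_states())
  ggplot2::ggplot(df, ggplot2::aes(.data$cycle, .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Model cycle (years post trial)", y = "Occupancy",
                  title = "Markov cohort trace") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
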