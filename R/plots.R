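#' Plot state occupancy over time
#'
#' Stacked-area chart of the seven state fractions across cycles.
#'
#' @param object An `esc_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esc_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(esc_states()),
                              names_to = "state", values_to = "fraction")
  long$state <- factor(long$state, levels = rev(esc_states()))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$cycle / 12, y = .data$fraction,
                               fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years since diagnosis", y = "Cohort fraction",
                  fill = "State",
                  title = sprintf("State occupancy, %s",
                                  toupper(attr(object, "arm")))) +
    ggplot2::theme_minimal()
}

#' Plot the PSA incremental cost-effectiveness plane
#'
#' Scatter of per-iteration incremental cost against incremental QALYs
#' (CRT relative to CRT+S), with the willingness-to-pay line.
#'
#' @param object An `esc_psa` from [run_psa()].
#' @param wtp Willingness-to-pay slope to draw; defaults to the analysis
#'   value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esc_psa <- function(object, wtp = object$settings$wtp, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs (CRT - CRT+S)",
                  y = "Incremental cost (CRT - CRT+S, $)",
                  title = "PSA incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves and frontier
#'
#' @param ceac_tbl A tibble from [ceac()] (or the `ceac` element of an
#'   `esc_psa`).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl) {
  if (inherits(ceac_tbl, "esc_psa")) ceac_tbl <- ceac_tbl$ceac
  long <- tidyr::pivot_longer(ceac_tbl, cols = c("ceac_crt", "ceac_crts"),
                              names_to = "strategy", values_to = "prob")
  long$strategy <- ifelse(long$strategy == "ceac_crt", "CRT", "CRT+S")
  frontier <- ceac_tbl
  frontier$prob <- ifelse(frontier$frontier_arm == "crt",
                          frontier$ceac_crt, frontier$ceac_crts)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$wtp, y = .data$prob,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = frontier,
                        ggplot2::aes(x = .data$wtp, y = .data$prob),
                        inherit.aes = FALSE, shape = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "P(cost-effective)",
                  colour = NULL,
                  title = "Acceptability curves (circles: frontier)") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the low-bound to the high-bound INMB per
#' parameter, widest at the top, with the base-case INMB as a vertical
#' line.
#'
#' @param tornado An `esc_tornado` from [one_way_dsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado) {
  tb <- as_tibble(tornado)
  tb$id <- factor(tb$id, levels = rev(tb$id))
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low,
                                       xend = .data$inmb_high,
                                       yend = .data$id),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "inmb_base"),
                        linetype = 2) +
    ggplot2::labs(x = "INMB of CRT vs CRT+S ($)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
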