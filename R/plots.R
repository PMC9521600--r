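#' Plot state occupancy over time
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- state_occupancy(object)
  df$years <- df$cycle * object$delta_years
  ggplot2::ggplot(df, ggplot2::aes(x = .data$years, y = .data$occupancy,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years", y = "Cohort fraction",
                  title = sprintf("Cohort trace: %s strategy", object$strategy$name)) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars from the NMB at the lower to the NMB at the upper bound of
#' each parameter, widest first, with a vertical base-case reference line.
#'
#' @param object An `owsa_result`.
#' @param top Number of parameters to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.owsa_result <- function(object, top = 10, ...) {
  df <- utils::head(as_tibble(object), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_at_low,
                                       xend = .data$nmb_at_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "nmb_base"), linetype = 2) +
    ggplot2::labs(x = sprintf("NMB, %s vs %s (CN¥ at WTP %.0f)",
                              attr(object, "reference"),
                              attr(object, "comparator"), attr(object, "wtp")),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param object A `ceac_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ceac_result <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"wtp",
                            names_to = "comparison", values_to = "probability")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CN¥/QALY)",
                  y = sprintf("P(%s cost-effective)", attr(object, "reference"))) +
    ggplot2::theme_minimal()
}
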