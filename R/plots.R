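#' Energy-ledger plot of an impact event
#'
#' @param object An `impact_history`.
#' @param ... Unused.
#' @return A ggplot of the kinetic, strain, contact and friction energies
#'   (and their total) against time.
#' @export
autoplot.impact_history <- function(object, ...) {
  df <- tidyr::pivot_longer(object$energies, -"time",
                            names_to = "component", values_to = "energy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$energy,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "energy (mJ)", colour = NULL)
}

#' Regional bar chart of a stress or pressure table
#'
#' @param object A `regional_stress_table` or `regional_pressure_table`.
#' @param ... Unused.
#' @return A ggplot with average and peak values per region.
#' @export
autoplot.regional_stress_table <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("average", "peak"),
                            names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value,
                                   fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "von Mises stress (MPa)", fill = NULL)
}

#' @rdname autoplot.regional_stress_table
#' @export
autoplot.regional_pressure_table <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("avg_pressure", "peak_pressure"),
                            names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value,
                                   fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "contact pressure (MPa)", fill = NULL)
}

#' Convergence report plot
#'
#' @param object A `convergence_report`.
#' @param ... Unused.
#' @return A ggplot of relative differences to the finest mesh per region,
#'   with the criterion band.
#' @export
autoplot.convergence_report <- function(object, ...) {
  crit <- attr(object, "criterion")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$region, y = 100 * .data$rel_diff,
                               fill = .data$resolution)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-100 * crit, 100 * crit),
                        linetype = 2) +
    ggplot2::labs(x = NULL, y = "difference to finest mesh (%)", fill = NULL)
}
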