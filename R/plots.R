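# ggplot2 displays for the main result objects.

#' Plot block thresholds against the optimal-threshold bands
#'
#' The qualitative optimality display: posterior medians and 95% credible
#' intervals of the block thresholds (points with error bars) over the
#' quantile bands of the posterior predictive optimal-threshold
#' distribution (shaded ribbons; the lightest shade is the 0.4-0.6 quantile
#' region), one panel per group.
#'
#' @param object A tibble from [threshold_optimality_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrddm_threshold_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$block)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$opt_tail_low, ymax = .data$opt_tail_high),
      fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$opt_q02, ymax = .data$opt_q08),
      fill = "darkgreen", alpha = 0.35) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$opt_q04, ymax = .data$opt_q06),
      fill = "darkgreen", alpha = 0.5) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$median, ymin = .data$ci_low,
                   ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "block", y = "decision threshold (evidence units)")
}

#' @rdname autoplot.rrddm_threshold_table
#' @param table A tibble from [threshold_optimality_table()].
#' @export
plot_threshold_optimality <- function(table, ...) {
  class(table) <- c("rrddm_threshold_table", class(table))
  autoplot(table, ...)
}

#' Trace plot of posterior draws
#'
#' @param object A `ddm_posterior`.
#' @param parameters Parameter names to show (default: first four).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddm_posterior <- function(object, parameters = NULL, ...) {
  long <- tidy(object)
  parameters <- parameters %||% head(unique(long$parameter), 4)
  long <- long[long$parameter %in% parameters, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     group = .data$chain)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = "value")
}

#' Recovery scatter of generating versus recovered values
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$generating, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered posterior median")
}
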