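#' Plot group mean +/- SD concentration-time curves
#'
#' Optional visual companion to [mean_sd_curve()]; requires ggplot2 (never
#' needed by the analysis itself).
#'
#' @param mean_curves A data.frame of stacked [mean_sd_curve()] rows.
#' @param threshold Optional horizontal reference line (ng/mL).
#' @param log_y Plot concentration on a log scale.
#' @return A ggplot object.
#' @export
plot_mean_curves <- function(mean_curves, threshold = NULL, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_mean_curves() requires the ggplot2 package")
  }
  d <- mean_curves
  d$lo <- pmax(d$mean_conc - d$sd_conc, 0)
  d$hi <- d$mean_conc + d$sd_conc
  p <- ggplot2::ggplot(d, ggplot2::aes(
         x = .data$time_h, y = .data$mean_conc, colour = .data$group_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time post-dose (h)", y = "Concentration (ng/mL)",
                  colour = "Group")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
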