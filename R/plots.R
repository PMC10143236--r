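# ggplot2 views of analysis and screening results.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_pointrange geom_col labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot the per-epoch course of an analysed session
#'
#' Activity, pulse rate and the two quality indices over epochs, with the
#' main sleep segment shaded.
#'
#' @param object A `wristhrv_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wristhrv_analysis <- function(object, ...) {
  ep <- object$epochs
  long <- tidyr::pivot_longer(
    ep[, c("epoch", "activity", "pulse_rate", "sqi_pr", "sqi_hrv")],
    -"epoch", names_to = "series", values_to = "value"
  )
  p <- ggplot(long, aes(x = .data$epoch, y = .data$value))
  seg <- object$segmentation
  if (!is.na(seg$onset)) {
    p <- p + geom_rect(
      data = tibble(xmin = seg$onset, xmax = seg$wake),
      aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p +
    geom_line(na.rm = TRUE, linewidth = 0.3) +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "epoch (min)", y = NULL,
         title = "Per-epoch pipeline outputs (shaded: main sleep)") +
    theme_minimal()
}

#' Plot cross-validated screening metrics
#'
#' Point-range plot of metric means with their 95% CIs over CV repeats.
#'
#' @param object A `wristhrv_screening`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wristhrv_screening <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$metric, y = .data$mean)) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    labs(x = NULL, y = "mean over CV repeats (95% CI)",
         title = sprintf("Screening performance (%d x %d-fold CV)",
                         object$n_repeats, object$n_folds)) +
    theme_minimal()
}
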