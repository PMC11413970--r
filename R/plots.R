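#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Plot simulation medians across subtype fractions
#'
#' One panel per metric, median across trials with the min-max ribbon,
#' against the subtype fraction. The characteristic shapes are: log2FC
#' creeping up but staying below the conventional significance line of
#' 1; AUC rising roughly linearly from 0.5; BCD jumping early and
#' peaking around a 40% subtype.
#'
#' @param object A `bcd_simulation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bcd_simulation
#' @export
autoplot.bcd_simulation <- function(object, ...) {
  summarize_trials(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$subtype_fraction)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min, ymax = .data$max),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "subtype fraction of cases",
      y = "metric value (median, min-max band)"
    ) +
    ggplot2::theme_minimal()
}

#' Case/control histogram for one analyte
#'
#' Overlaid per-group histograms of an analyte's (winsorized) values -
#' the visual check of whether a high BCD reflects a genuine second
#' mode in the cases.
#'
#' @inheritParams analyte_histogram
#' @return A ggplot.
#' @export
plot_analyte <- function(expr, pheno, analyte_id, bins = 30,
                         winsorized = TRUE) {
  analyte_histogram(expr, pheno, analyte_id,
    bins = bins, winsorized = winsorized
  ) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$bin_mid, y = .data$count, fill = .data$group
    )) +
    ggplot2::geom_col(position = "identity", alpha = 0.55) +
    ggplot2::labs(
      title = analyte_id,
      x = if (winsorized) "winsorized expression" else "expression",
      y = "samples"
    ) +
    ggplot2::theme_minimal()
}
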