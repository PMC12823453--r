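#' Plot a smoothed rRNA enrichment track
#'
#' Smoothed fold enrichment along the reference with a horizontal dotted
#' line at twofold and optional shaded footprint regions.
#'
#' @param track An `enrichment_track`.
#' @param regions Optional [region_annotation()] to shade.
#' @param threshold Horizontal reference line (default 2).
#' @return A ggplot object.
#' @export
plot_enrichment_track <- function(track, regions = region_annotation(),
                                  threshold = 2) {
  df <- data.frame(pos = seq_along(track$smoothed), fold = track$smoothed)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$fold))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$region),
      alpha = 0.2)
  }
  p +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "18S position (nt)", y = "fold enrichment (smoothed)",
                  fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot a metagene ratio profile
#'
#' Smoothed knockout-normalized ratio along the 300-bin standardized axis
#' with region boundaries marked at bins 100 and 200.
#'
#' @param metagene Data frame from [metagene_pipeline()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(metagene) {
  ggplot2::ggplot(metagene,
                  ggplot2::aes(x = .data$bin, y = .data$smoothed,
                               colour = .data$condition)) +
    ggplot2::geom_vline(xintercept = c(100, 200), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(
      breaks = c(50, 150, 250), labels = c("5'UTR", "CDS", "3'UTR")) +
    ggplot2::labs(x = NULL, y = "signal / knockout", colour = NULL) +
    ggplot2::theme_classic()
}
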