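#' Genome-wide AFD scan plot
#'
#' Plots the signed allele frequency difference of every variant along each
#' chromosome, with the association threshold drawn at `±threshold` and
#' called QTL intervals shaded.
#'
#' @param records AFD records from [compute_afd()].
#' @param qtl Optional QTL calls from [call_qtl()] to overlay.
#' @param threshold Association threshold drawn as horizontal lines.
#' @return A ggplot object.
#' @export
plot_afd_scan <- function(records, qtl = NULL, threshold = 0.75) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$afd)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::labs(x = "Position (Mbp)",
                  y = "Allele frequency difference (high - low)") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if (!is.null(qtl) && nrow(qtl) > 0) {
    pad <- 2 # Mbp, so single-marker QTL remain visible
    p <- p + ggplot2::geom_rect(
      data = qtl,
      ggplot2::aes(xmin = .data$start / 1e6 - pad,
                   xmax = .data$end / 1e6 + pad,
                   ymin = -1, ymax = 1),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    )
  }
  p
}
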