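#' Plot a pooled scan
#'
#' Manhattan-style plot of the smoothed G' statistic along the genome,
#' faceted by chromosome, with called peaks marked.
#'
#' @param object An `xqtl_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot xqtl_scan
#' @export
autoplot.xqtl_scan <- function(object, ...) {
  m <- object$markers
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$pos / 1e6, y = .data$G_smoothed)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "G' (tri-cube smoothed)") +
    ggplot2::theme_bw()
  if (nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$peaks,
      ggplot2::aes(xintercept = .data$pos / 1e6),
      linetype = "dashed", colour = "red"
    )
  }
  p
}

#' Plot a simulated trajectory
#'
#' Allele-frequency deviation from 0.5 along the genome, coloured by
#' generation.
#'
#' @param object A `bulk_sim` from [simulate_cross()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bulk_sim
#' @export
autoplot.bulk_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(x = .data$pos / 1e6, y = .data$deviation,
                 colour = factor(.data$generation),
                 group = .data$generation)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "allele frequency deviation",
                  colour = "generation") +
    ggplot2::theme_bw()
}

#' Plot a selection-coefficient fit
#'
#' Observed maximum-deviation trajectory over the best-fitting simulated
#' mean with its 95% envelope.
#'
#' @param object A `selcoef_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selcoef_fit
#' @export
autoplot.selcoef_fit <- function(object, ...) {
  best <- object$grid_fits[object$grid_fits$s == object$s_hat, ]
  ggplot2::ggplot(best, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_dev), colour = "steelblue") +
    ggplot2::geom_point(
      data = object$observed,
      ggplot2::aes(x = .data$generation, y = .data$deviation)
    ) +
    ggplot2::labs(
      x = "generation", y = "max deviation toward element allele",
      title = sprintf("best fit s = %.3g", object$s_hat)
    ) +
    ggplot2::theme_bw()
}

#' Plot a permutation FDR curve
#'
#' @param x An `eqtl_fdr` from [permutation_fdr()].
#' @return A ggplot of estimated FDR against the LOD threshold, with the
#'   chosen cutoff marked.
#' @export
plot_fdr_curve <- function(x) {
  cv <- x$curve[!is.na(x$curve$fdr), ]
  p <- ggplot2::ggplot(cv, ggplot2::aes(x = .data$lod, y = .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = x$target_fdr, linetype = "dashed") +
    ggplot2::labs(x = "LOD threshold", y = "estimated FDR") +
    ggplot2::theme_bw()
  if (!is.na(x$cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = x$cutoff, colour = "red",
                                 linetype = "dashed")
  }
  p
}
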