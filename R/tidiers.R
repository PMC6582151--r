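#' Tidy a pooled scan
#'
#' @param x An `xqtl_scan`.
#' @param ... Unused.
#' @return The per-marker scan tibble (`chrom`, `pos`, `cm`, `q`, `C`, `G`,
#'   `G_smoothed`, `p`).
#' @method tidy xqtl_scan
#' @export
tidy.xqtl_scan <- function(x, ...) x$markers

#' @rdname tidy.xqtl_scan
#' @return For `glance()`: a one-row tibble of scan metadata.
#' @method glance xqtl_scan
#' @export
glance.xqtl_scan <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$markers), n_excluded = x$params$n_excluded,
    null_mu = x$null$mu, null_sigma = x$null$sigma,
    half_width = x$params$half_width, variant = x$params$variant,
    alpha = x$params$alpha, n_peaks = nrow(x$peaks)
  )
}

#' Tidy a selection-coefficient fit
#'
#' @param x A `selcoef_fit`.
#' @param ... Unused.
#' @return Per-grid-value residual tibble (`s`, `residual`).
#' @method tidy selcoef_fit
#' @export
tidy.selcoef_fit <- function(x, ...) x$residuals

#' @rdname tidy.selcoef_fit
#' @method glance selcoef_fit
#' @export
glance.selcoef_fit <- function(x, ...) {
  tibble::tibble(
    s_hat = x$s_hat, residual = x$residual,
    n_generations = length(x$generations_used),
    grid_size = nrow(x$residuals)
  )
}

#' Tidy an eQTL mapping result
#'
#' @param x An `eqtl_result`.
#' @param ... Unused.
#' @return Per-probe best-marker tibble.
#' @method tidy eqtl_result
#' @export
tidy.eqtl_result <- function(x, ...) x$best

#' @rdname tidy.eqtl_result
#' @method glance eqtl_result
#' @export
glance.eqtl_result <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$lod), n_markers = ncol(x$lod),
    cutoff = if (is.null(x$cutoff)) NA_real_ else x$cutoff,
    n_significant = if (is.null(x$cutoff)) NA_integer_ else
      sum(x$best$significant)
  )
}

#' Tidy a simulation-based CI
#'
#' @param x A `sim_ci`.
#' @param ... Unused.
#' @return Tibble of per-iteration top-variant positions.
#' @method tidy sim_ci
#' @export
tidy.sim_ci <- function(x, ...) x$positions

#' @rdname tidy.sim_ci
#' @method glance sim_ci
#' @export
glance.sim_ci <- function(x, ...) {
  tibble::tibble(
    chrom = x$peak$chrom, peak_bp = x$peak$bp,
    ci_lo = x$ci[1], ci_hi = x$ci[2], width = diff(x$ci),
    level = x$level, iterations = x$iterations, off_chrom = x$off_chrom
  )
}
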