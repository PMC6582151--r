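#' Write and read scan results
#'
#' The scan is written as a TSV with columns `chrom`, `pos`, `G`,
#' `G_smoothed`, `p` (1-based inclusive coordinates), and the peaks as a
#' JSON sidecar (`<path>.peaks.json`) carrying one record per peak with
#' its position, p-value and, when available, simulation-based CI bounds.
#'
#' @param scan An `xqtl_scan` from [run_scan()].
#' @param path Output TSV path.
#' @param ci Optional `sim_ci` (or list of them) attaching CI bounds to the
#'   matching peak records.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, ci = NULL) {
  m <- scan$markers
  readr::write_tsv(
    tibble::tibble(chrom = m$chrom, pos = m$pos, G = m$G,
                   G_smoothed = m$G_smoothed, p = m$p),
    path
  )
  peaks <- scan$peaks
  if (inherits(ci, "sim_ci")) ci <- list(ci)
  records <- lapply(seq_len(nrow(peaks)), function(i) {
    rec <- list(
      chrom = peaks$chrom[i], pos = peaks$pos[i], p = peaks$p[i],
      run_start = peaks$run_start[i], run_end = peaks$run_end[i],
      n_markers = peaks$n_markers[i]
    )
    for (x in ci) {
      if (identical(x$peak$chrom, rec$chrom) && identical(x$peak$bp, rec$pos)) {
        rec$ci_lo <- x$ci[1]
        rec$ci_hi <- x$ci[2]
        rec$ci_method <- "simulation"
        rec$ci_level <- x$level
      }
    }
    rec
  })
  jsonlite::write_json(
    list(
      alpha = scan$params$alpha,
      null = list(mu = scan$null$mu, sigma = scan$null$sigma),
      coordinates = "1-based inclusive",
      peaks = records
    ),
    paste0(path, ".peaks.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scan
#' @return For `read_scan()`, a tibble of the per-marker scan columns.
#' @export
read_scan <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname write_scan
#' @return For `read_scan_peaks()`, the parsed peak sidecar list.
#' @export
read_scan_peaks <- function(path) {
  jsonlite::read_json(paste0(path, ".peaks.json"), simplifyVector = FALSE)
}
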