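#' Modified G statistic for pooled allele counts
#'
#' Contrasts allele counts between a high (selected) and a low (control)
#' pool at one SNV, absorbing baseline segregation distortion through the
#' control-pool allele-A frequency `q`. The numerator is
#' N = (1 - q)(n2 - n1) + q(n3 - n4). The default `"squared"` variant
#' returns N^2 / (2 C q (1 - q)), which is non-negative and reduces to
#' (n2 - n1)^2 / (2 C q (1 - q)) under equal pool depths (a chi-square-type
#' quantity compatible with the log-normal null); the
#' `"as-printed-linear"` variant returns N / (2 C q (1 - q)) and can be
#' negative. The methods vignette discusses the default.
#'
#' @param n1,n3 Allele-A and allele-B counts in the high pool (vectorised).
#' @param n2,n4 Allele-A and allele-B counts in the low pool.
#' @param q Baseline allele-A frequency (from the control pool), in (0, 1).
#' @param C Depth of coverage at the SNV (> 0).
#' @param variant `"squared"` (default) or `"as-printed-linear"`.
#' @return Numeric vector of G values.
#' @export
#' @examples
#' g_statistic(60, 40, 40, 60, q = 0.4, C = 100) # 400/48
g_statistic <- function(n1, n2, n3, n4, q, C,
                        variant = c("squared", "as-printed-linear")) {
  variant <- match.arg(variant)
  if (any(q <= 0 | q >= 1)) {
    stop("q must lie strictly in (0, 1); filter monomorphic markers upstream")
  }
  if (any(C <= 0)) stop("coverage C must be positive")
  num <- (1 - q) * (n2 - n1) + q * (n3 - n4)
  den <- 2 * C * q * (1 - q)
  if (variant == "squared") num^2 / den else num / den
}

#' Baseline frequency and coverage per marker
#'
#' `q` is the allele-A frequency in the control (low) pool,
#' `q = n2 / (n2 + n4)`; coverage follows the chosen convention (default:
#' mean of the two pools' depths at the marker). Markers with zero control
#' depth, `q` of exactly 0 or 1, or non-positive coverage are flagged for
#' exclusion rather than clamped, because the G statistic divides by
#' q(1 - q).
#'
#' @param tab An [allele_counts()] table.
#' @param coverage_convention `"mean"`, `"min"` or `"control"`.
#' @return The table with columns `q`, `C` and logical `exclude` appended.
#' @export
estimate_q_and_c <- function(tab, coverage_convention = c("mean", "min", "control")) {
  coverage_convention <- match.arg(coverage_convention)
  depth_high <- tab$n1 + tab$n3
  depth_low <- tab$n2 + tab$n4
  q <- ifelse(depth_low > 0, tab$n2 / depth_low, NA_real_)
  C <- switch(coverage_convention,
    mean = (depth_high + depth_low) / 2,
    min = pmin(depth_high, depth_low),
    control = depth_low
  )
  tab$q <- q
  tab$C <- C
  tab$exclude <- is.na(q) | q <= 0 | q >= 1 | C <= 0
  tab
}

#' Tri-cube smoothing of the G statistic in genetic distance
#'
#' For each focal marker s, markers j on the same chromosome within
#' `half_width` cM form the window W; each gets weight
#' (1 - D_j^3)^3 / S_W with D_j = |cM_j - cM_s| / half_width and S_W the
#' sum of raw weights, so weights are non-negative, sum to one, peak at the
#' focal marker and vanish at the window edge. The default half-width of
#' 12.5 cM (a 25 cM window) is the lower bound of the range recommended
#' for bulked-segregant G smoothing.
#'
#' @param g Raw G values.
#' @param cm Genetic positions (cM), from [bp_to_cm()].
#' @param chrom Chromosome labels, parallel to `g`.
#' @param half_width Window half-width in cM.
#' @return Numeric vector of smoothed G' values, in input order.
#' @export
tricube_smooth <- function(g, cm, chrom, half_width = 12.5) {
  stopifnot(length(g) == length(cm), length(g) == length(chrom), half_width > 0)
  code <- match(chrom, unique(chrom))
  ord <- order(code, cm)
  out <- numeric(length(g))
  out[ord] <- cpp_tricube(as.numeric(g[ord]), as.numeric(cm[ord]),
                          as.integer(code[ord]), half_width)
  out
}

#' Robust log-normal null fit for smoothed G'
#'
#' Location and scale of log G' are estimated by the median and the
#' normal-consistent MAD (x 1.4826), so that a minority of true-signal
#' markers in the upper tail barely perturbs the null. Non-positive G'
#' values (possible only under the linear statistic variant) are excluded
#' from the fit.
#'
#' @param gprime Smoothed G' values.
#' @return List of class `lognormal_null` with `mu`, `sigma`, `n_used`.
#' @export
fit_null_lognormal <- function(gprime) {
  x <- gprime[is.finite(gprime) & gprime > 0]
  if (length(x) < 100) {
    stop("fewer than 100 positive G' values: log-normal null fit is unstable")
  }
  lx <- log(x)
  mu <- stats::median(lx)
  sigma <- stats::mad(lx) # constant = 1.4826, normal-consistent
  if (sigma == 0) stop("degenerate null: MAD of log G' is zero")
  structure(list(mu = mu, sigma = sigma, n_used = length(x)),
            class = "lognormal_null")
}

#' Upper-tail log-normal p-values for G'
#'
#' @param gprime Smoothed G' values.
#' @param null A `lognormal_null` from [fit_null_lognormal()].
#' @return p-values in (0, 1], strictly decreasing in G'. Non-positive G'
#'   values get p = 1.
#' @export
lognormal_pvalues <- function(gprime, null) {
  p <- rep(1, length(gprime))
  pos <- is.finite(gprime) & gprime > 0
  p[pos] <- stats::plnorm(gprime[pos], null$mu, null$sigma, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

#' Call peaks from a scanned marker table
#'
#' Contiguous runs of markers with p < alpha are merged per chromosome;
#' each run's minimum-p marker is the peak (leftmost on ties).
#'
#' @param markers Tibble with `chrom`, `pos`, `p` (marker order respected
#'   within chromosome).
#' @param alpha Significance level.
#' @return Tibble of peaks: `chrom`, `pos`, `p`, `run_start`, `run_end`,
#'   `n_markers` (possibly empty).
#' @export
call_peaks <- function(markers, alpha) {
  out <- list()
  for (ch in unique(markers$chrom)) {
    sub <- markers[markers$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    sig <- sub$p < alpha
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run <- sub[starts[k]:ends[k], ]
      best <- which.min(run$p) # which.min takes the first (leftmost) minimum
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, pos = run$pos[best], p = run$p[best],
        run_start = min(run$pos), run_end = max(run$pos),
        n_markers = nrow(run)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = numeric(), p = numeric(),
      run_start = numeric(), run_end = numeric(), n_markers = integer()
    ))
  }
  dplyr::bind_rows(out)
}

#' Run the pooled-scan statistical pipeline
#'
#' Filters markers with undefined baseline frequency, computes the modified
#' G statistic, smooths it with a tri-cube kernel in genetic distance, fits
#' the robust log-normal null, converts G' to upper-tail p-values and calls
#' peaks. Fully deterministic.
#'
#' @param counts An [allele_counts()] table (or a data frame coercible to
#'   one).
#' @param map A [genetic_map()] covering the count table's chromosomes.
#' @param half_width Smoothing half-width in cM (default 12.5).
#' @param variant G-statistic variant (see [g_statistic()]).
#' @param alpha Peak-calling significance level (raw p, no genome-wide
#'   correction; recorded in the result metadata).
#' @param coverage_convention See [estimate_q_and_c()].
#' @return An object of class `xqtl_scan`: list with `markers` (tibble:
#'   `chrom`, `pos`, `cm`, `q`, `C`, `G`, `G_smoothed`, `p`), `peaks`,
#'   `null` (the fit), and `params`.
#' @export
run_scan <- function(counts, map, half_width = 12.5,
                     variant = c("squared", "as-printed-linear"),
                     alpha = 1e-5,
                     coverage_convention = c("mean", "min", "control")) {
  variant <- match.arg(variant)
  coverage_convention <- match.arg(coverage_convention)
  if (!inherits(counts, "allele_counts")) counts <- allele_counts(counts)
  tab <- estimate_q_and_c(counts, coverage_convention)
  n_excl <- sum(tab$exclude)
  if (n_excl > 0) {
    rlang::inform(sprintf(
      "excluding %d marker(s) with monomorphic control pool or zero coverage",
      n_excl
    ))
  }
  tab <- tab[!tab$exclude, ]
  if (nrow(tab) == 0) stop("no markers left after filtering")

  # genetic positions; markers outside the anchored span take the nearest
  # anchor's cM and are flagged
  cm <- numeric(nrow(tab))
  flagged <- logical(nrow(tab))
  for (ch in unique(tab$chrom)) {
    i <- tab$chrom == ch
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0) stop("chromosome ", ch, " of the counts not in map")
    bp <- pmin(pmax(tab$pos[i], min(sub$bp)), max(sub$bp))
    flagged[i] <- bp != tab$pos[i]
    cm[i] <- bp_to_cm(map, ch, bp)
  }
  if (any(flagged)) {
    rlang::inform(sprintf(
      "%d marker(s) outside the map span assigned the nearest anchor's cM",
      sum(flagged)
    ))
  }

  G <- g_statistic(tab$n1, tab$n2, tab$n3, tab$n4, tab$q, tab$C, variant)
  Gp <- tricube_smooth(G, cm, tab$chrom, half_width)
  null <- fit_null_lognormal(Gp)
  p <- lognormal_pvalues(Gp, null)
  markers <- tibble::tibble(
    chrom = tab$chrom, pos = tab$pos, cm = cm, q = tab$q, C = tab$C,
    G = G, G_smoothed = Gp, p = p, off_map = flagged
  )
  structure(
    list(
      markers = markers,
      peaks = call_peaks(markers, alpha),
      null = null,
      params = list(half_width = half_width, variant = variant, alpha = alpha,
                    coverage_convention = coverage_convention,
                    n_excluded = n_excl)
    ),
    class = "xqtl_scan"
  )
}

#' @export
print.xqtl_scan <- function(x, ...) {
  cat(sprintf(
    "<xqtl_scan> %d markers (%d excluded); variant = %s, half-width = %g cM\n",
    nrow(x$markers), x$params$n_excluded, x$params$variant, x$params$half_width
  ))
  cat(sprintf("  null: log-normal(mu = %.4f, sigma = %.4f)\n",
              x$null$mu, x$null$sigma))
  cat(sprintf("  %d peak(s) at alpha = %g\n", nrow(x$peaks), x$params$alpha))
  invisible(x)
}
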