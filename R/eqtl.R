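#' Filter expression probes by presence
#'
#' Probes observed (non-missing) in at least `min_presence` of samples are
#' retained; the boundary case (exactly the threshold) is kept.
#'
#' @param expr Numeric matrix, probes x samples (rownames = probe IDs).
#' @param min_presence Minimum fraction of non-missing samples (default 2/3).
#' @return The filtered matrix; removals are reported as a message.
#' @export
filter_probes <- function(expr, min_presence = 2 / 3) {
  stopifnot(is.matrix(expr), nrow(expr) > 0)
  present <- rowMeans(!is.na(expr))
  keep <- present >= min_presence
  if (!any(keep)) stop("all probes removed by the presence filter")
  if (any(!keep)) {
    rlang::inform(sprintf("removed %d probe(s) present in < %.3g of samples",
                          sum(!keep), min_presence))
  }
  expr[keep, , drop = FALSE]
}

#' Normalise rows to mean zero and variance one
#'
#' Each row is centred and scaled over its non-missing entries. The
#' operation is idempotent. Constant rows cannot be scaled and are an
#' error (filter them first).
#'
#' @param m Numeric matrix (probes or markers x samples).
#' @return The row-normalised matrix.
#' @export
normalize_rows <- function(m) {
  stopifnot(is.matrix(m))
  mu <- rowMeans(m, na.rm = TRUE)
  centred <- m - mu
  s <- sqrt(apply(centred, 1, stats::var, na.rm = TRUE))
  if (any(!is.finite(s)) || any(s == 0)) {
    stop("constant row(s) cannot be normalised to variance one")
  }
  centred / s
}

#' LOD score from a squared correlation
#'
#' LOD = -n ln(1 - R^2) / (2 ln 10); zero at R^2 = 0 and strictly
#' increasing in both R^2 and n.
#'
#' @param r2 Squared Pearson correlation(s), in `[0, 1)`.
#' @param n Sample count(s) behind each correlation (>= 3); recycled.
#' @return LOD score(s).
#' @export
#' @examples
#' lod_from_r2(0.2, 100) # about 4.85
lod_from_r2 <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) stop("R^2 must lie in [0, 1)")
  if (any(n < 3, na.rm = TRUE)) stop("n must be at least 3")
  -n * log(1 - r2) / (2 * log(10))
}

# Probe x marker LOD matrix, pairwise-complete in the presence of missing
# expression values (per-pair n enters the LOD transform).
lod_matrix <- function(expr, geno) {
  if (ncol(expr) != ncol(geno)) stop("expression and genotype sample counts differ")
  r <- stats::cor(t(expr), t(geno), use = "pairwise.complete.obs")
  if (any(is.na(expr))) {
    n <- crossprod(t(!is.na(expr)) * 1, t(!is.na(geno)) * 1)
  } else {
    n <- matrix(ncol(expr), nrow(expr), nrow(geno))
  }
  r2 <- pmin(r^2, 1 - 1e-12) # guard exact collinearity against log(0)
  lod_from_r2(r2, n)
}

#' Map expression QTLs by correlation
#'
#' Normalises the expression and genotype matrices to row mean zero and
#' variance one, computes every probe x marker Pearson correlation,
#' transforms it to a LOD score (see [lod_from_r2()]) and reports each
#' probe's best marker. Missing expression values are handled by
#' pairwise-complete correlations with the per-pair sample count in the
#' LOD transform.
#'
#' @param expr Probes x samples matrix.
#' @param geno Markers x samples matrix (biallelic codes), sample-aligned
#'   with `expr`.
#' @param cutoff Optional genome-wide LOD cutoff (e.g. from
#'   [permutation_fdr()]); probes at or above it are flagged significant.
#' @return Object of class `eqtl_result`: list with `lod` (matrix), `best`
#'   (tibble: `probe`, `marker`, `lod`, `significant`), `cutoff`.
#' @export
map_eqtls <- function(expr, geno, cutoff = NULL) {
  expr <- normalize_rows(expr)
  geno <- normalize_rows(geno)
  lod <- lod_matrix(expr, geno)
  best_idx <- apply(lod, 1, which.max)
  best <- tibble::tibble(
    probe = if (is.null(rownames(expr))) as.character(seq_len(nrow(expr))) else rownames(expr),
    marker = if (is.null(rownames(geno))) as.character(best_idx) else rownames(geno)[best_idx],
    lod = lod[cbind(seq_len(nrow(lod)), best_idx)]
  )
  best$significant <- if (is.null(cutoff)) NA else best$lod >= cutoff
  structure(list(lod = lod, best = best, cutoff = cutoff),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat(sprintf("<eqtl_result> %d probes x %d markers", nrow(x$lod), ncol(x$lod)))
  if (!is.null(x$cutoff)) {
    cat(sprintf("; %d probe(s) with LOD >= %.3g", sum(x$best$significant),
                x$cutoff))
  }
  cat("\n")
  invisible(x)
}

#' Permutation-based FDR threshold for eQTL mapping
#'
#' Sample identities of the expression matrix are permuted `n_perm` times
#' (genotypes untouched, preserving marker LD) and the per-probe maximum
#' LOD recomputed. At each candidate threshold t, FDR(t) is the mean
#' permuted count of probes with max LOD >= t divided by the observed
#' count; the cutoff is the smallest t on a `grid_step`-spaced grid with
#' FDR(t) at or below `target_fdr`. Deterministic given the seed set
#' before the call.
#'
#' @param expr,geno Matrices as in [map_eqtls()].
#' @param n_perm Number of permutations (default 100).
#' @param target_fdr Target false-discovery rate (default 0.05).
#' @param grid_step Spacing of the candidate LOD grid (default 0.1).
#' @return List of class `eqtl_fdr`: `cutoff` (NA when no threshold
#'   attains the target), `fdr_at_cutoff`, `curve` (tibble: `lod`,
#'   `n_observed`, `mean_permuted`, `fdr`).
#' @export
permutation_fdr <- function(expr, geno, n_perm = 100, target_fdr = 0.05,
                            grid_step = 0.1) {
  expr <- normalize_rows(expr)
  geno <- normalize_rows(geno)
  obs_max <- apply(lod_matrix(expr, geno), 1, max)
  perm_max <- matrix(NA_real_, nrow(expr), n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample.int(ncol(expr))
    perm_max[, k] <- apply(lod_matrix(expr[, perm, drop = FALSE], geno), 1, max)
  }
  grid <- seq(grid_step, max(obs_max, perm_max) + grid_step, by = grid_step)
  n_obs <- vapply(grid, function(t) sum(obs_max >= t), 0)
  n_perm_mean <- vapply(grid, function(t) mean(colSums(perm_max >= t)), 0)
  fdr <- ifelse(n_obs > 0, pmin(n_perm_mean / n_obs, 1), NA_real_)
  curve <- tibble::tibble(lod = grid, n_observed = n_obs,
                          mean_permuted = n_perm_mean, fdr = fdr)
  ok <- which(!is.na(fdr) & fdr <= target_fdr & n_obs > 0)
  if (all(n_obs == 0)) {
    rlang::inform("no observed discoveries at any threshold; cutoff undefined")
    cutoff <- NA_real_
    fdr_at <- NA_real_
  } else if (length(ok) == 0) {
    rlang::inform("no threshold attains the target FDR; cutoff undefined")
    cutoff <- NA_real_
    fdr_at <- NA_real_
  } else {
    cutoff <- grid[ok[1]]
    fdr_at <- fdr[ok[1]]
  }
  structure(
    list(cutoff = cutoff, fdr_at_cutoff = fdr_at, curve = curve,
         n_perm = n_perm, target_fdr = target_fdr),
    class = "eqtl_fdr"
  )
}

#' @export
print.eqtl_fdr <- function(x, ...) {
  if (is.na(x$cutoff)) {
    cat("<eqtl_fdr> no cutoff attains the target FDR of", x$target_fdr, "\n")
  } else {
    cat(sprintf("<eqtl_fdr> LOD cutoff %.2f (estimated FDR %.3g, target %g)\n",
                x$cutoff, x$fdr_at_cutoff, x$target_fdr))
  }
  invisible(x)
}

#' Read a probes/markers x samples matrix from TSV
#'
#' First column = row IDs, header = sample IDs.
#' @param path TSV path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  m
}
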