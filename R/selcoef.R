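#' Per-generation maximum deviation toward the element allele
#'
#' Summarises a trajectory table as the statistic used for
#' selection-coefficient fitting: for each generation, the maximum over
#' markers in a window of the allele-frequency deviation toward the
#' element-bearing allele. The default window is the element's whole
#' chromosome; `"genome"` searches all markers.
#'
#' @param trajectory Tibble with `generation`, `chrom`, `pos`, `freq_b`
#'   (as produced by [simulate_cross()]).
#' @param element A [drive_element()] (its `allele` sets the deviation
#'   direction; allele A means deviation = 0.5 - freq_b).
#' @param window `"chromosome"` (default) or `"genome"`.
#' @return Tibble with `generation`, `deviation`.
#' @export
max_deviation_trajectory <- function(trajectory, element,
                                     window = c("chromosome", "genome")) {
  window <- match.arg(window)
  tr <- trajectory
  if (window == "chromosome") tr <- tr[tr$chrom == element$chrom, ]
  if (nrow(tr) == 0) stop("no markers in the deviation window")
  dev <- if (element$allele == "A") 0.5 - tr$freq_b else tr$freq_b - 0.5
  tr$dev <- dev
  out <- dplyr::summarise(
    dplyr::group_by(tr, .data$generation),
    deviation = max(.data$dev), .groups = "drop"
  )
  tibble::as_tibble(out)
}

#' Simulate drive trajectories over a grid of selection coefficients
#'
#' For each penetrance value s on the grid, replicate populations are
#' propagated with the drive element active and the per-generation
#' maximum-deviation statistic is recorded; the per-generation mean and a
#' 2.5-97.5% envelope across replicates form the reference trajectories
#' that [fit_selection_coefficient()] matches against. Replicates that go
#' extinct are dropped with a message; more than 20% dropped for any s is
#' an error.
#'
#' @param element A [drive_element()]; its `s` field is overridden by the
#'   grid values.
#' @param map,markers Genome backbone.
#' @param grid Selection-coefficient grid (default 20 values spanning 0-1).
#' @param replicates Populations per grid value (default 50).
#' @param popsize Worms per population (default 10,000; used as both F1
#'   size and cap).
#' @param generations Generations per population (default 20).
#' @param progeny Progeny per mated female.
#' @param window Deviation window (see [max_deviation_trajectory()]).
#' @return Object of class `s_grid`: tibble with `s`, `generation`,
#'   `mean_dev`, `lo`, `hi`, `n_rep`, plus the design as attributes.
#' @export
simulate_s_grid <- function(element, map, markers,
                            grid = seq(0, 1, length.out = 20),
                            replicates = 50, popsize = 10000,
                            generations = 20, progeny = 10,
                            window = "chromosome") {
  stopifnot(all(grid >= 0), all(grid <= 1))
  rows <- list()
  for (s in grid) {
    el <- drive_element(element$chrom, element$bp, s, element$allele)
    cfg <- sim_config(
      generations = generations, founders = popsize, cap = popsize,
      progeny = progeny, drive = el
    )
    devs <- list()
    dropped <- 0
    for (r in seq_len(replicates)) {
      sim <- tryCatch(simulate_cross(cfg, map, markers), error = function(e) NULL)
      if (is.null(sim)) {
        dropped <- dropped + 1
        next
      }
      devs[[length(devs) + 1]] <- max_deviation_trajectory(sim$trajectory, el,
                                                           window)$deviation
    }
    if (dropped > 0) {
      rlang::inform(sprintf("s = %.3f: dropped %d extinct replicate(s)", s, dropped))
    }
    if (dropped > 0.2 * replicates) {
      stop("more than 20% of replicates extinct at s = ", s)
    }
    dmat <- do.call(cbind, devs)
    rows[[length(rows) + 1]] <- tibble::tibble(
      s = s, generation = seq_len(generations),
      mean_dev = rowMeans(dmat),
      lo = apply(dmat, 1, stats::quantile, probs = 0.025),
      hi = apply(dmat, 1, stats::quantile, probs = 0.975),
      n_rep = ncol(dmat)
    )
  }
  structure(dplyr::bind_rows(rows), class = c("s_grid", "tbl_df", "tbl", "data.frame"),
            element = element, popsize = popsize, replicates = replicates)
}

#' Fit a selection coefficient by trajectory matching
#'
#' The best-fit s is the grid member minimising the sum over generations of
#' the absolute difference between the simulated mean trajectory and the
#' observed one (absolute differences, so deviations of opposite sign
#' cannot cancel). No interpolation between grid values is performed.
#'
#' @param observed Tibble with `generation`, `deviation` (an observed
#'   maximum-deviation trajectory, e.g. from
#'   [max_deviation_trajectory()] or [average_across_experiments()]).
#' @param grid_fits An `s_grid` from [simulate_s_grid()].
#' @return Object of class `selcoef_fit`: list with `s_hat`, `residual`,
#'   `residuals` (per-s tibble), `observed`, `generations_used`.
#' @export
fit_selection_coefficient <- function(observed, grid_fits) {
  gens <- intersect(observed$generation, unique(grid_fits$generation))
  if (length(gens) == 0) {
    stop("observed and simulated trajectories share no generations")
  }
  obs <- observed$deviation[match(gens, observed$generation)]
  svals <- unique(grid_fits$s)
  resid <- vapply(svals, function(s) {
    sub <- grid_fits[grid_fits$s == s, ]
    sim <- sub$mean_dev[match(gens, sub$generation)]
    sum(abs(sim - obs))
  }, 0)
  best <- which.min(resid) # first (smallest s) on exact ties
  structure(
    list(
      s_hat = svals[best], residual = resid[best],
      residuals = tibble::tibble(s = svals, residual = resid),
      observed = tibble::tibble(generation = gens, deviation = obs),
      generations_used = gens,
      grid_fits = grid_fits
    ),
    class = "selcoef_fit"
  )
}

#' @export
print.selcoef_fit <- function(x, ...) {
  cat(sprintf("<selcoef_fit> s_hat = %.4g (residual %.4g over %d generations)\n",
              x$s_hat, x$residual, length(x$generations_used)))
  invisible(x)
}

#' Average observed trajectories across experiments
#'
#' Per-generation arithmetic mean of the deviation statistic, computed on
#' the intersection of the experiments' generation grids.
#'
#' @param trajectories List of tibbles with `generation`, `deviation`.
#' @return Tibble with `generation`, `deviation`.
#' @export
average_across_experiments <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  gens <- Reduce(intersect, lapply(trajectories, function(t) t$generation))
  if (length(gens) == 0) stop("experiments share no generations")
  gens <- sort(gens)
  devs <- vapply(
    trajectories,
    function(t) t$deviation[match(gens, t$generation)],
    numeric(length(gens))
  )
  if (length(gens) == 1) devs <- matrix(devs, nrow = 1)
  tibble::tibble(generation = gens, deviation = rowMeans(devs))
}
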