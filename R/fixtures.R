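#' Generate a nematode-like fixture genome
#'
#' Builds a genetic map and marker grid emulating the C. elegans genome:
#' six chromosomes (~100 Mb total, the last flagged as X) of roughly 50 cM
#' each, with, under the `"arm-biased"` profile, recombination concentrated
#' on the chromosome arms (the outer thirds carry most of the map length,
#' the centre is recombination-poor) as in the real species; the
#' `"uniform"` profile makes cM strictly proportional to bp. Markers are
#' placed uniformly in bp with random distinct nucleotide identities.
#'
#' @param n_chrom Number of chromosomes (default 6; the last one is the X).
#' @param bp_length Chromosome bp lengths, recycled (defaults approximate
#'   the C. elegans karyotype).
#' @param cm_length Total map length per chromosome in cM (default 50).
#' @param profile `"arm-biased"` (default) or `"uniform"`.
#' @param n_markers Total marker count, split across chromosomes in
#'   proportion to bp length (>= 2 per chromosome required).
#' @param seed Optional seed for marker placement.
#' @param dir Optional directory; when given, `map.tsv` and `markers.tsv`
#'   are written there.
#' @return List with `map` (a [genetic_map()]) and `markers`
#'   (a [marker_grid()]).
#' @export
make_fixture_genome <- function(n_chrom = 6, bp_length = NULL, cm_length = 50,
                                profile = c("arm-biased", "uniform"),
                                n_markers = 2000, seed = NULL, dir = NULL) {
  profile <- match.arg(profile)
  stopifnot(n_chrom >= 1, cm_length > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bp_length)) {
    bp_length <- c(15.1e6, 15.3e6, 13.8e6, 17.5e6, 20.9e6, 17.7e6)
  }
  bp_length <- rep_len(bp_length, n_chrom)
  labels <- c("I", "II", "III", "IV", "V", "X")
  chroms <- if (n_chrom <= 6) labels[seq_len(n_chrom)] else
    c(labels[1:5], paste0("chr", 6:(n_chrom - 1)), "X")[seq_len(n_chrom)]
  chroms[n_chrom] <- "X"

  anchors <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    L <- bp_length[c]
    if (profile == "uniform") {
      tibble::tibble(chrom = chroms[c], bp = c(1, L), cm = c(0, cm_length))
    } else {
      # outer-third arms carry 80% of the map, the centre third 20%
      tibble::tibble(
        chrom = chroms[c],
        bp = c(1, round(L / 3), round(2 * L / 3), L),
        cm = cm_length * c(0, 0.4, 0.6, 1)
      )
    }
  }))
  map <- genetic_map(anchors, x_chrom = "X")

  per_chrom <- pmax(2L, round(n_markers * bp_length / sum(bp_length)))
  if (any(n_markers * bp_length / sum(bp_length) < 2)) {
    stop("n_markers too small: fewer than 2 markers on some chromosome")
  }
  bases <- c("A", "C", "G", "T")
  markers <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(c) {
    m <- per_chrom[c]
    pos <- sort(sample.int(bp_length[c] - 2, m) + 1)
    while (anyDuplicated(pos) > 0) {
      pos <- sort(unique(c(pos, sample.int(bp_length[c] - 2, m) + 1)))[seq_len(m)]
    }
    a <- sample(bases, m, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), "")
    tibble::tibble(chrom = chroms[c], bp = pos, allele_a = a, allele_b = unname(b))
  }))
  markers <- marker_grid(markers, map = map)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genetic_map(map, file.path(dir, "map.tsv"))
    readr::write_tsv(tibble::as_tibble(markers), file.path(dir, "markers.tsv"))
  }
  list(map = map, markers = markers)
}

#' Simulate a complete mapping experiment fixture
#'
#' End-to-end simulated experiments emitting exactly the inputs the scan
#' consumes, plus a ground-truth record for tests:
#' `"drug-selection"` propagates a segregant pool, truncation-selects the
#' top fraction against a random control subset; `"two-tail-sort"`
#' contrasts the top and bottom tails of the score distribution;
#' `"neutral-timecourse"` propagates with no causal locus and contrasts two
#' independent random subsets, also recording the per-generation
#' trajectory.
#'
#' @param design One of `"drug-selection"`, `"two-tail-sort"`,
#'   `"neutral-timecourse"`.
#' @param genome A list with `map` and `markers` (see
#'   [make_fixture_genome()]).
#' @param config A [sim_config()] (its `seed` makes the fixture
#'   reproducible).
#' @param ve Variance explained by the causal locus (selection designs).
#' @param causal Causal marker as `list(chrom =, bp =)`; default: a random
#'   marker.
#' @param truncation Selected fraction (default 0.05).
#' @param coverage Simulated read depth.
#' @param dir Optional output directory for `counts.tsv`, `truth.json` and
#'   (neutral design) `trajectory.tsv`.
#' @return List with `counts` (an [allele_counts()]), `truth` (list), and
#'   `trajectory` (tibble or NULL).
#' @export
make_fixture_experiment <- function(design = c("drug-selection", "two-tail-sort",
                                               "neutral-timecourse"),
                                    genome, config = sim_config(), ve = 0.2,
                                    causal = NULL, truncation = 0.05,
                                    coverage = 100, dir = NULL) {
  design <- match.arg(design)
  map <- genome$map
  markers <- genome$markers
  sim <- simulate_cross(config, map, markers)
  pop <- sim$population
  trajectory <- NULL
  truth <- list(design = design, seed = config$seed,
                generations = config$generations, coverage = coverage,
                causal = list())

  if (design == "neutral-timecourse") {
    n_pool <- max(2L, round(pop$n * truncation))
    high <- subset_pop(pop, sample.int(pop$n, n_pool))
    low <- subset_pop(pop, sample.int(pop$n, n_pool))
    counts <- simulate_pool_counts(high, low, markers, coverage)
    trajectory <- sim$trajectory
  } else {
    if (is.null(causal)) {
      k <- sample.int(nrow(markers), 1)
      causal <- list(chrom = markers$chrom[k], bp = markers$bp[k])
    }
    model <- effect_size_model(causal$chrom, causal$bp, ve, truncation)
    if (design == "drug-selection") {
      pools <- truncation_select(pop, model)
      counts <- simulate_pool_counts(pools$selected, pools$control, markers,
                                     coverage)
    } else {
      g <- genotype_at(pop, model$chrom, model$bp)
      s <- g + stats::rnorm(pop$n, 0, sqrt(displacement_variance(model, stats::var(g))))
      n_sel <- max(1L, round(pop$n * truncation))
      ord <- order(-s, stats::runif(pop$n))
      high <- subset_pop(pop, ord[seq_len(n_sel)])
      low <- subset_pop(pop, rev(ord)[seq_len(n_sel)])
      counts <- simulate_pool_counts(high, low, markers, coverage)
    }
    truth$causal <- list(chrom = causal$chrom, bp = causal$bp, ve = ve,
                         truncation = truncation)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_allele_counts(counts, file.path(dir, "counts.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(trajectory)) {
      readr::write_tsv(trajectory, file.path(dir, "trajectory.tsv"))
    }
  }
  list(counts = counts, truth = truth, trajectory = trajectory)
}
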