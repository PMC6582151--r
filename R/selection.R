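#' Toxin-antidote drive element
#'
#' Models a linked sperm-delivered toxin / zygotically expressed antidote
#' pair (the peel-1/zeel-1 configuration): a zygote dies with probability
#' `s` if and only if its father carries at least one copy of the
#' element-bearing allele and the zygote inherits zero copies. The mother's
#' genotype never triggers lethality. In a cross of two heterozygotes with
#' `s = 1` this yields the classic 25% embryonic lethality.
#'
#' @param chrom Autosome label carrying the element.
#' @param bp Position of the element locus.
#' @param s Penetrance in `[0, 1]`: 0 no lethality, 1 fully penetrant.
#' @param allele Which allele carries the element; `"A"` (the reference,
#'   N2-like parent) by default.
#' @return A list of class `drive_element`.
#' @export
drive_element <- function(chrom, bp, s, allele = c("A", "B")) {
  allele <- match.arg(allele)
  stopifnot(s >= 0, s <= 1)
  structure(list(chrom = chrom, bp = bp, s = s, allele = allele),
            class = "drive_element")
}

#' Fitness locus acting on male mating success
#'
#' Per-genotype weights multiplying a male's probability of being chosen
#' to mate. Weights are indexed by genotype at the locus (AA, AB, BB) and
#' multiply across loci.
#'
#' @param chrom,bp Locus position.
#' @param w_aa,w_ab,w_bb Positive finite genotype weights.
#' @return A list of class `fitness_locus`.
#' @export
fitness_locus <- function(chrom, bp, w_aa = 1, w_ab = 1, w_bb = 1) {
  w <- c(w_aa, w_ab, w_bb)
  if (any(!is.finite(w)) || any(w <= 0)) stop("fitness weights must be positive and finite")
  structure(list(chrom = chrom, bp = bp, w_aa = w_aa, w_ab = w_ab, w_bb = w_bb),
            class = "fitness_locus")
}

#' Simulate toxin-antidote zygote survival
#'
#' Vectorised over zygotes: survival is certain unless the father carries
#' the element (>= 1 copy) and the zygote carries none, in which case the
#' zygote dies with probability `s`. The maternal genotype is accepted for
#' interface completeness but does not enter the rule (the toxin is
#' sperm-delivered).
#'
#' @param mother_geno,father_geno,zygote_geno Element-allele copy numbers
#'   (0, 1 or 2); recycled against each other.
#' @param s Penetrance.
#' @return Logical vector: `TRUE` if the zygote survives.
#' @export
drive_survives <- function(mother_geno, father_geno, zygote_geno, s) {
  n <- max(length(mother_geno), length(father_geno), length(zygote_geno))
  father_geno <- rep_len(father_geno, n)
  zygote_geno <- rep_len(zygote_geno, n)
  at_risk <- father_geno >= 1 & zygote_geno == 0
  !(at_risk & stats::runif(n) < s)
}

#' Male fitness weight
#'
#' Product over fitness loci of the genotype weight; 1 for an empty locus
#' list. Hemizygous X genotypes use the homozygote weights.
#'
#' @param pop A `bulk_pop`.
#' @param loci List of [fitness_locus()] specs (possibly empty or NULL).
#' @param ids Individual indices (default: all).
#' @return Numeric vector of weights.
#' @export
male_fitness_weight <- function(pop, loci, ids = seq_len(pop$n)) {
  w <- rep(1, length(ids))
  if (is.null(loci) || length(loci) == 0) return(w)
  x <- attr(pop$map, "x_chrom")
  for (l in loci) {
    d <- genotype_at(pop, l$chrom, l$bp)[ids]
    wt <- c(l$w_aa, l$w_ab, l$w_bb)
    hemi <- identical(l$chrom, x) & pop$sex[ids] == 1L
    idx <- ifelse(hemi, 2 * d + 1, d + 1)
    w <- w * wt[idx]
  }
  w
}

#' Effect-size model for truncation selection
#'
#' A causal locus explaining a fraction `ve` of phenotypic variance. Each
#' individual's genotype at the locus is coded g in {0, 1, 2} (copies of
#' the selected allele) and a displacement d ~ Normal(0, sigma^2) is added
#' to give the score S = g + d; the top `truncation` fraction by S are the
#' "survivors". Two sigma^2 parameterisations are available:
#' `"variance-consistent"` (default), sigma^2 = Vl (1 - Ve) / Ve, which
#' makes Var(g)/Var(S) equal Ve exactly in expectation; and `"as-printed"`,
#' sigma^2 = (1 - Ve) / (Ve Vl). Vl is the realised variance of the g
#' vector. The two coincide when Vl = 1; the methods vignette discusses the
#' choice of default.
#'
#' @param chrom,bp Causal locus.
#' @param ve Variance explained, in (0, 1).
#' @param truncation Fraction of the pool selected (default 0.05).
#' @param variant `"variance-consistent"` or `"as-printed"`.
#' @param allele Which allele increases the score (default `"B"`).
#' @return A list of class `effect_size_model`.
#' @export
effect_size_model <- function(chrom, bp, ve, truncation = 0.05,
                              variant = c("variance-consistent", "as-printed"),
                              allele = c("B", "A")) {
  variant <- match.arg(variant)
  allele <- match.arg(allele)
  stopifnot(ve > 0, ve < 1, truncation > 0, truncation < 1)
  structure(
    list(chrom = chrom, bp = bp, ve = ve, truncation = truncation,
         variant = variant, allele = allele),
    class = "effect_size_model"
  )
}

#' Displacement variance of an effect-size model
#' @param model An [effect_size_model()].
#' @param vl Realised variance of the genotype vector g.
#' @return sigma^2 of the normal displacement.
#' @export
displacement_variance <- function(model, vl) {
  if (vl <= 0) stop("monomorphic causal locus: Var(g) = 0")
  switch(model$variant,
    "variance-consistent" = vl * (1 - model$ve) / model$ve,
    "as-printed" = (1 - model$ve) / (model$ve * vl)
  )
}

#' Truncation selection on a simulated pool
#'
#' Scores every individual as S = g + d (see [effect_size_model()]),
#' selects the top `truncation` fraction (ties at the boundary broken
#' uniformly at random), and draws a control subset uniformly at random
#' from the whole pool.
#'
#' @param pop A `bulk_pop` (the expanded segregant pool).
#' @param model An [effect_size_model()].
#' @param control_size Size of the control pool (default: same as selected).
#' @return List with `selected` and `control` `bulk_pop`s, plus the
#'   realised `vl`, `sigma2` and the score vector `s` (invisible inputs to
#'   diagnostics).
#' @export
truncation_select <- function(pop, model, control_size = NULL) {
  g <- genotype_at(pop, model$chrom, model$bp)
  if (model$allele == "A") {
    ploidy <- ifelse(
      identical(model$chrom, attr(pop$map, "x_chrom")) & pop$sex == 1L, 1L, 2L
    )
    g <- ploidy - g
  }
  vl <- stats::var(g)
  sigma2 <- displacement_variance(model, vl) # errors when vl == 0
  s <- g + stats::rnorm(pop$n, 0, sqrt(sigma2))
  n_sel <- max(1L, round(pop$n * model$truncation))
  ord <- order(-s, stats::runif(pop$n))
  sel_idx <- ord[seq_len(n_sel)]
  if (is.null(control_size)) control_size <- n_sel
  ctl_idx <- sample.int(pop$n, control_size)
  list(
    selected = subset_pop(pop, sel_idx),
    control = subset_pop(pop, ctl_idx),
    vl = vl, sigma2 = sigma2, score = s
  )
}

#' Simulate pooled sequencing counts
#'
#' Per marker and pool, the allele-B read count is Binomial(coverage,
#' pool frequency of B) and the allele-A count is the complement, emulating
#' shotgun sequencing of pooled DNA at fixed depth.
#'
#' @param selected,control `bulk_pop`s (high and low pools).
#' @param markers A [marker_grid()].
#' @param coverage Read depth per marker per pool (scalar or per-marker).
#' @return An [allele_counts()] tibble.
#' @export
simulate_pool_counts <- function(selected, control, markers, coverage = 100) {
  m <- nrow(markers)
  coverage <- rep_len(coverage, m)
  fh <- marker_freqs(selected, markers)$freq_b
  fl <- marker_freqs(control, markers)$freq_b
  n3 <- stats::rbinom(m, coverage, fh)
  n4 <- stats::rbinom(m, coverage, fl)
  allele_counts(tibble::tibble(
    chrom = markers$chrom, pos = markers$bp,
    n1 = coverage - n3, n2 = coverage - n4, n3 = n3, n4 = n4
  ))
}
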