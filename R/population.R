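#' @keywords internal
new_bulk_pop <- function(n, sex, chrom, map) {
  structure(
    list(n = as.integer(n), sex = as.integer(sex), chrom = chrom, map = map),
    class = "bulk_pop"
  )
}

# Packed empty-haplotype chromosome block for n individuals.
pack_uniform_chrom <- function(n, start1, start2) {
  list(
    start1 = rep(as.integer(start1), n),
    off1 = integer(n + 1),
    cuts1 = numeric(0),
    start2 = rep(as.integer(start2), n),
    off2 = integer(n + 1),
    cuts2 = numeric(0)
  )
}

#' Found an F1 segregant population
#'
#' Creates the F1 generation of an A-strain female x B-strain male cross:
#' every autosome carries one A and one B haplotype; F1 females carry a
#' maternal A and a paternal B X chromosome, while F1 males are hemizygous
#' for the maternal A X chromosome (X/0 sex determination, so sex follows
#' the paternal X-bearing or nullo-X gamete).
#'
#' @param n Number of F1 individuals.
#' @param map A [genetic_map()] (its `x_chrom` attribute marks the X).
#' @param sex_ratio Probability that an individual is female (default 0.5).
#' @return A population object of class `bulk_pop`.
#' @export
founder_population <- function(n, map, sex_ratio = 0.5) {
  stopifnot(n >= 1, sex_ratio > 0, sex_ratio < 1)
  sex <- ifelse(stats::runif(n) < sex_ratio, 0L, 1L)
  x <- attr(map, "x_chrom")
  chrom <- lapply(map_chromosomes(map), function(ch) {
    blk <- pack_uniform_chrom(n, 0L, 1L) # maternal A, paternal B
    if (identical(ch, x)) blk$start2[sex == 1L] <- NA_integer_
    blk
  })
  new_bulk_pop(n, sex, chrom, map)
}

#' Construct an inbred parental population
#'
#' All haplotypes share a single parental origin; used to build parental
#' individuals for explicit crosses in examples and tests.
#'
#' @param n Number of individuals.
#' @param map A [genetic_map()].
#' @param origin `"A"` or `"B"`.
#' @param sex Optional integer vector (0 female, 1 male), recycled;
#'   defaults to alternating sexes.
#' @return A `bulk_pop`.
#' @export
inbred_population <- function(n, map, origin = c("A", "B"), sex = NULL) {
  origin <- match.arg(origin)
  o <- if (origin == "A") 0L else 1L
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), n)
  sex <- as.integer(rep_len(sex, n))
  x <- attr(map, "x_chrom")
  chrom <- lapply(map_chromosomes(map), function(ch) {
    blk <- pack_uniform_chrom(n, o, o)
    if (identical(ch, x)) blk$start2[sex == 1L] <- NA_integer_
    blk
  })
  new_bulk_pop(n, sex, chrom, map)
}

#' @export
print.bulk_pop <- function(x, ...) {
  cat(sprintf(
    "<bulk_pop> %d individuals (%d female, %d male), %d chromosomes\n",
    x$n, sum(x$sex == 0L), sum(x$sex == 1L), length(x$chrom)
  ))
  invisible(x)
}

#' Population size
#' @param pop A `bulk_pop`.
#' @return Integer count of individuals.
#' @export
pop_size <- function(pop) pop$n

#' Subset a population
#' @param pop A `bulk_pop`.
#' @param idx 1-based individual indices.
#' @return A `bulk_pop` with the selected individuals.
#' @export
subset_pop <- function(pop, idx) {
  stopifnot(all(idx >= 1), all(idx <= pop$n))
  packed <- cpp_subset_pop(unclass(pop)[c("n", "sex", "chrom")],
                           as.integer(idx))
  new_bulk_pop(packed$n, packed$sex, packed$chrom, pop$map)
}

# Concatenate populations sharing a map.
bind_pops <- function(pops) {
  n <- sum(vapply(pops, function(p) p$n, 0L))
  sex <- unlist(lapply(pops, function(p) p$sex))
  chrom <- lapply(seq_along(pops[[1]]$chrom), function(c) {
    list(
      start1 = unlist(lapply(pops, function(p) p$chrom[[c]]$start1)),
      off1 = bind_offsets(lapply(pops, function(p) p$chrom[[c]]$off1)),
      cuts1 = unlist(lapply(pops, function(p) p$chrom[[c]]$cuts1)),
      start2 = unlist(lapply(pops, function(p) p$chrom[[c]]$start2)),
      off2 = bind_offsets(lapply(pops, function(p) p$chrom[[c]]$off2)),
      cuts2 = unlist(lapply(pops, function(p) p$chrom[[c]]$cuts2))
    )
  })
  new_bulk_pop(n, sex, chrom, pops[[1]]$map)
}

bind_offsets <- function(offs) {
  shift <- 0L
  out <- 0L
  for (o in offs) {
    out <- c(out, o[-1] + shift)
    shift <- shift + o[length(o)]
  }
  as.integer(out)
}

#' Marker allele frequencies of a population
#'
#' Frequency of allele B at each marker, counting two alleles per diploid
#' individual and one per hemizygous male X.
#'
#' @param pop A `bulk_pop`.
#' @param markers A [marker_grid()].
#' @return Tibble with `chrom`, `pos`, `freq_b` and the allele total `n_alleles`.
#' @export
marker_freqs <- function(pop, markers) {
  chrom0 <- match(markers$chrom, map_chromosomes(pop$map)) - 1L
  if (any(is.na(chrom0))) stop("marker chromosome absent from the population's map")
  cnt <- cpp_marker_counts(
    unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
    as.integer(chrom0), as.numeric(markers$bp)
  )
  tibble::tibble(
    chrom = markers$chrom, pos = markers$bp,
    freq_b = cnt$nB / cnt$tot, n_alleles = cnt$tot
  )
}

#' B-allele dosage at one locus
#'
#' @param pop A `bulk_pop`.
#' @param chrom Chromosome label.
#' @param bp Position.
#' @return Integer vector: copies of allele B per individual (0/1 for
#'   hemizygous males at an X locus, 0/1/2 otherwise).
#' @export
genotype_at <- function(pop, chrom, bp) {
  ci <- match(chrom, map_chromosomes(pop$map))
  if (is.na(ci)) stop("chromosome ", chrom, " absent from the population's map")
  cpp_dosage(unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
             as.integer(ci), as.numeric(bp))
}

#' Haplotype segments of one individual
#'
#' Expands the sparse change-point representation into explicit
#' parental-origin segments, mainly for inspection and invariant checks.
#'
#' @param pop A `bulk_pop`.
#' @param id Individual index.
#' @return Tibble with `chrom`, `hap` (1 or 2), `start_bp`, `end_bp`,
#'   `origin` (`"A"` or `"B"`). Absent haplotypes (male X) are omitted.
#' @export
haplotype_segments <- function(pop, id) {
  stopifnot(id >= 1, id <= pop$n)
  chroms <- map_chromosomes(pop$map)
  lens <- chromosome_lengths(pop$map)
  out <- list()
  for (c in seq_along(chroms)) {
    blk <- pop$chrom[[c]]
    for (h in 1:2) {
      start <- blk[[paste0("start", h)]][id]
      if (is.na(start)) next
      off <- blk[[paste0("off", h)]]
      cuts <- blk[[paste0("cuts", h)]][seq2(off[id] + 1, off[id + 1])]
      bnd <- c(0, cuts, lens[[c]])
      orig <- (start + seq_len(length(cuts) + 1) - 1) %% 2
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chroms[c], hap = h,
        start_bp = bnd[-length(bnd)], end_bp = bnd[-1],
        origin = c("A", "B")[orig + 1]
      )
    }
  }
  dplyr::bind_rows(out)
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)
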