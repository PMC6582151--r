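#' Simulation configuration
#'
#' Bundles the demographic parameters of a forward simulation: a starting
#' F1 of `founders` individuals is propagated for `generations`
#' non-overlapping generations; every female mates once with a male sampled
#' in proportion to his fitness weight, contributes `progeny` offspring,
#' and the surviving offspring are down-sampled without replacement to
#' `cap`. Defaults mirror a laboratory segregant-pool design: 1,000 F1
#' founders, a 50,000-worm cap, 10 progeny per mated female, and a
#' probability of 0.5 that each chromosome undergoes a single crossover
#' per meiosis.
#'
#' @param generations Number of generations, counting the F1 as generation 1.
#' @param founders F1 population size.
#' @param cap Population cap per generation (>= founders).
#' @param progeny Progeny per mated female.
#' @param p_xo Per-chromosome single-crossover probability per meiosis.
#' @param sex_ratio Probability that a founder is female.
#' @param seed Optional integer seed; [simulate_cross()] seeds R's RNG with
#'   it so runs are byte-reproducible.
#' @param fitness_loci Optional list of [fitness_locus()] specs.
#' @param drive Optional [drive_element()] spec.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(generations = 10, founders = 1000, cap = 50000,
                       progeny = 10, p_xo = 0.5, sex_ratio = 0.5,
                       seed = NULL, fitness_loci = NULL, drive = NULL) {
  stopifnot(
    generations >= 1, founders >= 2, cap >= founders, progeny >= 1,
    p_xo >= 0, p_xo <= 1, sex_ratio > 0, sex_ratio < 1
  )
  structure(
    list(
      generations = as.integer(generations), founders = as.integer(founders),
      cap = as.integer(cap), progeny = as.integer(progeny), p_xo = p_xo,
      sex_ratio = sex_ratio, seed = seed,
      fitness_loci = fitness_loci, drive = drive
    ),
    class = "sim_config"
  )
}

fitness_to_cpp <- function(loci, map) {
  if (is.null(loci) || length(loci) == 0) return(NULL)
  lapply(loci, function(l) {
    ci <- match(l$chrom, map_chromosomes(map))
    if (is.na(ci)) stop("fitness locus chromosome ", l$chrom, " not in map")
    list(chrom = as.integer(ci), bp = as.numeric(l$bp),
         w = as.numeric(c(l$w_aa, l$w_ab, l$w_bb)))
  })
}

drive_to_cpp <- function(drive, map) {
  if (is.null(drive)) return(NULL)
  ci <- match(drive$chrom, map_chromosomes(map))
  if (is.na(ci)) stop("drive locus chromosome ", drive$chrom, " not in map")
  if (identical(drive$chrom, attr(map, "x_chrom"))) {
    stop("the drive element must sit on an autosome")
  }
  list(chrom = as.integer(ci), bp = as.numeric(drive$bp),
       allele = if (drive$allele == "B") 1L else 0L, s = drive$s)
}

#' Draw gametes from one parent
#'
#' Per chromosome and gamete, with probability `p_xo` a single crossover is
#' placed uniformly in genetic (cM) distance, converted to bp via the map,
#' and one of the two reciprocal recombinant products is returned; otherwise
#' one parental haplotype is copied unchanged. A male parent's X is copied
#' without recombination (he is hemizygous); whether a sperm carries the X
#' at all is decided during [mate()].
#'
#' @param pop A `bulk_pop`.
#' @param parent Individual index.
#' @param n Number of gametes.
#' @param p_xo Per-chromosome crossover probability.
#' @return A `gamete_set`: per chromosome, packed haplotypes (`start`,
#'   `off`, `cuts`) for the `n` gametes.
#' @export
make_gametes <- function(pop, parent, n, p_xo = 0.5) {
  stopifnot(parent >= 1, parent <= pop$n, n >= 1)
  g <- cpp_gametes(unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
                   as.integer(parent), as.integer(n), p_xo)
  structure(list(chrom = g, n = as.integer(n), map = pop$map),
            class = "gamete_set")
}

#' Crossover counts per gamete
#' @param gametes A `gamete_set` from [make_gametes()].
#' @return Tibble with `gamete`, `chrom`, `n_breakpoints`.
#' @export
crossover_counts <- function(gametes) {
  chroms <- map_chromosomes(gametes$map)
  dplyr::bind_rows(lapply(seq_along(chroms), function(c) {
    tibble::tibble(
      gamete = seq_len(gametes$n), chrom = chroms[c],
      n_breakpoints = diff(gametes$chrom[[c]]$off)
    )
  }))
}

#' Parental origin of gametes at given positions
#' @param gametes A `gamete_set`.
#' @param chrom Chromosome label.
#' @param bp Positions (vectorised).
#' @return Integer matrix (gametes x positions): 0 = A origin, 1 = B origin.
#' @export
gamete_origins <- function(gametes, chrom, bp) {
  c <- match(chrom, map_chromosomes(gametes$map))
  blk <- gametes$chrom[[c]]
  out <- matrix(NA_integer_, gametes$n, length(bp))
  for (i in seq_len(gametes$n)) {
    cuts <- blk$cuts[seq2(blk$off[i] + 1, blk$off[i + 1])]
    for (j in seq_along(bp)) {
      out[i, j] <- bitwXor(blk$start[i], sum(cuts < bp[j]) %% 2)
    }
  }
  out
}

#' Mate two individuals
#'
#' Each progeny is formed from one maternal and one paternal gamete. Sex
#' follows the paternal gamete: X-bearing sperm give females, nullo-X sperm
#' give males (who therefore inherit their X from the mother). When a drive
#' element is supplied, progeny are filtered by toxin-antidote lethality
#' (see [drive_element()]), so fewer than `n_progeny` may be returned.
#'
#' @param pop A `bulk_pop` holding both parents.
#' @param mother,father Individual indices; the mother must be female and
#'   the father male.
#' @param n_progeny Number of zygotes to form.
#' @param drive Optional [drive_element()].
#' @param p_xo Per-chromosome crossover probability.
#' @return A `bulk_pop` of surviving progeny.
#' @export
mate <- function(pop, mother, father, n_progeny, drive = NULL, p_xo = 0.5) {
  if (pop$sex[mother] != 0L || pop$sex[father] != 1L) {
    stop("mate() requires a female mother and a male father")
  }
  packed <- cpp_mate(unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
                     as.integer(mother), as.integer(father),
                     as.integer(n_progeny), p_xo, drive_to_cpp(drive, pop$map))
  new_bulk_pop(packed$n, packed$sex, packed$chrom, pop$map)
}

#' Advance a population by one non-overlapping generation
#'
#' Every female mates once with a male drawn with probability proportional
#' to his fitness weight (uniform when no fitness loci are configured) and
#' contributes `config$progeny` zygotes. Zygotes are filtered by drive
#' lethality, pooled, and down-sampled without replacement to `config$cap`.
#'
#' @param pop A `bulk_pop` containing both sexes.
#' @param config A [sim_config()].
#' @return The next-generation `bulk_pop`.
#' @export
propagate <- function(pop, config) {
  packed <- cpp_propagate(
    unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
    config$p_xo, config$progeny, config$cap,
    fitness_to_cpp(config$fitness_loci, pop$map),
    drive_to_cpp(config$drive, pop$map)
  )
  new_bulk_pop(packed$n, packed$sex, packed$chrom, pop$map)
}

#' Simulate a multigenerational segregant pool
#'
#' Founds an F1 population from an A x B cross (generation 1) and
#' propagates it for `config$generations - 1` further non-overlapping
#' generations, recording the B-allele frequency at every marker after each
#' generation. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param map A [genetic_map()].
#' @param markers A [marker_grid()] at which to record frequencies.
#' @param record `"all"` records frequencies after every generation,
#'   `"final"` only for the last one (cheaper for power studies that only
#'   scan the terminal pool).
#' @return A list of class `bulk_sim` with elements `trajectory` (tibble:
#'   `generation`, `chrom`, `pos`, `freq_b`, `deviation` = freq_b - 0.5)
#'   and `population` (the final `bulk_pop`).
#' @export
simulate_cross <- function(config, map, markers, record = c("all", "final")) {
  record <- match.arg(record)
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- founder_population(config$founders, map, config$sex_ratio)
  traj <- vector("list", config$generations)
  rec <- function(gen, pop) {
    f <- marker_freqs(pop, markers)
    tibble::tibble(generation = gen, chrom = f$chrom, pos = f$pos,
                   freq_b = f$freq_b, deviation = f$freq_b - 0.5)
  }
  if (record == "all") traj[[1]] <- rec(1L, pop)
  g <- 2L
  while (g <= config$generations) {
    pop <- tryCatch(
      propagate(pop, config),
      error = function(e) stop("generation ", g, ": ", conditionMessage(e))
    )
    if (record == "all" || g == config$generations) traj[[g]] <- rec(g, pop)
    g <- g + 1L
  }
  if (config$generations == 1L && record == "final") traj[[1]] <- rec(1L, pop)
  structure(
    list(trajectory = dplyr::bind_rows(traj), population = pop,
         config = config),
    class = "bulk_sim"
  )
}

#' @export
print.bulk_sim <- function(x, ...) {
  cat(sprintf(
    "<bulk_sim> %d generation(s); final population of %d; %d markers tracked\n",
    max(x$trajectory$generation), x$population$n,
    length(unique(paste(x$trajectory$chrom, x$trajectory$pos)))
  ))
  invisible(x)
}

#' Expand a population into a large segregant pool
#'
#' One additional random-mating generation without a cap, sized to
#' `target`. With `times > 1`, independent expansions are concatenated,
#' emulating the splitting of one source population onto many plates.
#'
#' @param pop Source `bulk_pop`.
#' @param target Number of individuals per expansion.
#' @param config A [sim_config()] supplying `p_xo` and any drive element
#'   (fitness weighting also applies if configured).
#' @param times Number of independent expansions to concatenate.
#' @return A `bulk_pop` of (about, under drive lethality) `target * times`
#'   individuals.
#' @export
expand_pool <- function(pop, target, config = sim_config(), times = 1) {
  n_f <- sum(pop$sex == 0L)
  if (n_f == 0L || n_f == pop$n) stop("source population lacks one sex")
  progeny <- ceiling(target / n_f)
  one <- function() {
    packed <- cpp_propagate(
      unclass(pop)[c("n", "sex", "chrom")], map_to_cpp(pop$map),
      config$p_xo, as.integer(progeny), as.integer(target),
      fitness_to_cpp(config$fitness_loci, pop$map),
      drive_to_cpp(config$drive, pop$map)
    )
    new_bulk_pop(packed$n, packed$sex, packed$chrom, pop$map)
  }
  pools <- lapply(seq_len(times), function(i) one())
  if (times == 1) pools[[1]] else bind_pops(pools)
}
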