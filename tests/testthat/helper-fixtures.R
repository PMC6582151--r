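# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# 6-chromosome arm-biased fixture genome, cached across test files
small_genome <- function(n_markers = 600) {
  key <- paste0("g", n_markers)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture_genome(n_markers = n_markers, seed = 42)
  }
  .fixture_cache[[key]]
}

# single uniform chromosome, for closed-form recombination checks
one_chrom_map <- function(l_bp = 1e7, l_cm = 50) {
  genetic_map(data.frame(chrom = "I", bp = c(1, l_bp), cm = c(0, l_cm)))
}

# Deterministic genotype-frequency recursion for a paternal-toxin /
# zygotic-antidote element at one autosomal locus under random mating:
# zygotes with zero element copies from an element-carrying father die
# with probability s. Independent oracle for the drive dynamics; returns
# the element-allele frequency per generation (generation 1 = F1, all het).
drive_recursion <- function(s, generations) {
  g <- c(0, 1, 0) # genotype frequencies for 0/1/2 element copies
  freq <- numeric(generations)
  freq[1] <- g[2] / 2 + g[3]
  if (generations == 1) return(freq)
  zygote_dist <- function(m, f) {
    pm <- m / 2
    pf <- f / 2
    c(
      (1 - pm) * (1 - pf),
      pm * (1 - pf) + (1 - pm) * pf,
      pm * pf
    )
  }
  for (t in 2:generations) {
    nxt <- c(0, 0, 0)
    for (m in 0:2) {
      for (f in 0:2) {
        z <- zygote_dist(m, f)
        w <- c(if (f >= 1) 1 - s else 1, 1, 1)
        nxt <- nxt + g[m + 1] * g[f + 1] * z * w
      }
    }
    g <- nxt / sum(nxt)
    freq[t] <- g[2] / 2 + g[3]
  }
  freq
}

# Pearson correlation computed from first principles (oracle for cor()
# based LOD mapping).
manual_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
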