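test_that("an A x B cross yields fully heterozygous F1 autosomes", {
  g <- small_genome()
  set.seed(31)
  parents <- bulkqtl:::bind_pops(list(
    inbred_population(1, g$map, "A", sex = 0L),
    inbred_population(1, g$map, "B", sex = 1L)
  ))
  kids <- mate(parents, 1, 2, 500)
  expect_equal(kids$n, 500)
  for (ch in c("I", "III", "V")) {
    bp <- chromosome_lengths(g$map)[[ch]] / 2
    expect_true(all(genotype_at(kids, ch, bp) == 1L))
  }
  # F1 females are het on X; F1 males carry only the maternal A
  xg <- genotype_at(kids, "X", 1e6)
  expect_true(all(xg[kids$sex == 0] == 1L))
  expect_true(all(xg[kids$sex == 1] == 0L))
  expect_error(mate(parents, 2, 1, 5), "female mother and a male father")
})

test_that("X/0 segregation gives a balanced sex ratio", {
  g <- small_genome()
  set.seed(32)
  pop <- founder_population(100, g$map)
  kids <- mate(pop, which(pop$sex == 0)[1], which(pop$sex == 1)[1], 10000)
  frac_f <- mean(kids$sex == 0)
  expect_lt(abs(frac_f - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("F2 genotypes segregate 1:2:1", {
  g <- small_genome()
  set.seed(33)
  f1 <- founder_population(2000, g$map)
  f2 <- propagate(f1, sim_config(founders = 2000, cap = 10000))
  geno <- genotype_at(f2, "II", 8e6)
  n <- length(geno)
  expect_gte(n, 9000) # progeny count follows the binomial founder sex split
  tab <- tabulate(geno + 1L, 3)
  chi <- stats::chisq.test(tab, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("the population cap is enforced exactly", {
  g <- small_genome()
  set.seed(34)
  pop <- founder_population(200, g$map)
  nxt <- propagate(pop, sim_config(founders = 200, cap = 300))
  expect_equal(nxt$n, 300)
})

test_that("propagation fails informatively when a sex is missing", {
  g <- small_genome()
  set.seed(35)
  pop <- inbred_population(10, g$map, "A", sex = 0L) # all female
  expect_error(propagate(pop, sim_config(founders = 10, cap = 100)),
               "lacks one sex")
})

test_that("a male-fitness locus drives the favoured allele upward", {
  g <- small_genome()
  set.seed(36)
  locus <- fitness_locus("III", 7e6, w_aa = 1, w_ab = 1.5, w_bb = 2)
  cfg <- sim_config(generations = 6, founders = 400, cap = 400,
                    fitness_loci = list(locus))
  mk <- marker_grid(data.frame(chrom = "III", bp = 7e6), map = g$map)
  freqs <- replicate(30, {
    sim <- simulate_cross(cfg, g$map, mk)
    sim$trajectory$freq_b
  })
  mean_traj <- rowMeans(freqs)
  expect_equal(mean_traj[1], 0.5) # F1
  expect_true(all(diff(mean_traj) > -0.005)) # monotone in expectation
  expect_gt(mean_traj[6], 0.55)
})

test_that("simulate_cross is byte-reproducible given a seed", {
  g <- small_genome()
  cfg <- sim_config(generations = 4, founders = 200, cap = 400, seed = 99)
  a <- simulate_cross(cfg, g$map, g$markers)
  b <- simulate_cross(cfg, g$map, g$markers)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population$chrom, b$population$chrom)
})

test_that("a one-generation simulation is the exactly heterozygous F1", {
  g <- small_genome()
  cfg <- sim_config(generations = 1, founders = 500, cap = 500, seed = 7)
  sim <- simulate_cross(cfg, g$map, g$markers)
  auto <- sim$trajectory[sim$trajectory$chrom != "X", ]
  expect_true(all(auto$freq_b == 0.5))
  expect_true(all(auto$deviation == 0))
})

test_that("drive-locus allele frequency tracks the deterministic recursion", {
  g <- small_genome()
  set.seed(37)
  el <- drive_element("I", 5e6, s = 1)
  cfg <- sim_config(generations = 8, founders = 400, cap = 400, drive = el)
  mk <- marker_grid(data.frame(chrom = "I", bp = 5e6), map = g$map)
  sims <- replicate(40, {
    sim <- simulate_cross(cfg, g$map, mk)
    1 - sim$trajectory$freq_b # element allele is A
  })
  mean_freq <- rowMeans(sims)
  oracle <- drive_recursion(1, 8)
  expect_true(all(diff(mean_freq) > -0.01)) # non-decreasing in expectation
  expect_lt(max(abs(mean_freq - oracle)), 0.03)
})

test_that("expand_pool reaches the target and preserves frequencies", {
  g <- small_genome()
  set.seed(38)
  cfg <- sim_config(generations = 3, founders = 300, cap = 600)
  sim <- simulate_cross(cfg, g$map, g$markers, record = "final")
  big <- expand_pool(sim$population, 6000, cfg)
  expect_equal(big$n, 6000)
  f0 <- marker_freqs(sim$population, g$markers)$freq_b
  f1 <- marker_freqs(big, g$markers)$freq_b
  # expansion adds one generation of sampling noise around the source
  expect_lt(mean(abs(f1 - f0)), 0.05)
  expect_lt(max(abs(f1 - f0)), 0.2)
  two <- expand_pool(sim$population, 500, cfg, times = 2)
  expect_equal(two$n, 1000)
  set.seed(1)
  e1 <- expand_pool(sim$population, 500, cfg)
  set.seed(2)
  e2 <- expand_pool(sim$population, 500, cfg)
  expect_false(identical(e1$chrom, e2$chrom))
})

test_that("neutral propagation conserves allele frequencies on autosomes", {
  g <- small_genome()
  set.seed(39)
  cfg <- sim_config(generations = 6, founders = 500, cap = 500)
  grand <- replicate(15, {
    sim <- simulate_cross(cfg, g$map, g$markers, record = "final")
    tr <- sim$trajectory
    mean(tr$freq_b[tr$chrom != "X"])
  })
  expect_lt(abs(mean(grand) - 0.5), 0.01)
  # the X starts at 1/3 B under an A-female x B-male founding cross
  sim <- simulate_cross(sim_config(generations = 1, founders = 4000, seed = 4),
                        g$map, g$markers)
  x <- sim$trajectory[sim$trajectory$chrom == "X", ]
  expect_lt(abs(mean(x$freq_b) - 1 / 3), 0.03)
})
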