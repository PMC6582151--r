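test_that("toxin-antidote lethality follows the paternal-toxin rule", {
  set.seed(41)
  # het x het: zygote element dosage ~ (1/4, 1/2, 1/4)
  n <- 20000
  z <- stats::rbinom(n, 1, 0.5) + stats::rbinom(n, 1, 0.5)
  lethal <- 1 - mean(drive_survives(1, 1, z, s = 1))
  expect_lt(abs(lethal - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # father without the element delivers no toxin, ever
  expect_true(all(drive_survives(2, 0, rep(0, 1000), s = 1)))
  # het father x element-free mother at partial penetrance:
  # half the zygotes are at risk, so lethality = 0.5 * s
  z2 <- stats::rbinom(n, 1, 0.5)
  lethal2 <- 1 - mean(drive_survives(0, 1, z2, s = 0.55))
  expect_lt(abs(lethal2 - 0.275), 3 * sqrt(0.275 * 0.725 / n))
})

test_that("male fitness weights multiply across loci", {
  g <- small_genome()
  set.seed(42)
  f1 <- founder_population(10, g$map) # autosomal genotypes all AB
  expect_equal(male_fitness_weight(f1, NULL), rep(1, 10))
  expect_equal(male_fitness_weight(f1, list()), rep(1, 10))
  l1 <- fitness_locus("I", 5e6, w_aa = 1, w_ab = 1.5, w_bb = 2)
  expect_equal(male_fitness_weight(f1, list(l1)), rep(1.5, 10))
  # homozygous A individuals: product of the two AA weights
  aa <- inbred_population(5, g$map, "A")
  l2 <- fitness_locus("II", 5e6, w_aa = 0.5, w_ab = 1, w_bb = 3)
  l3 <- fitness_locus("IV", 5e6, w_aa = 2, w_ab = 1, w_bb = 0.25)
  expect_equal(male_fitness_weight(aa, list(l2, l3)), rep(1, 5))
  expect_error(fitness_locus("I", 1, w_aa = 0), "positive")
})

test_that("the noiseless limit of truncation selection picks the top genotype", {
  g <- small_genome()
  set.seed(43)
  cfg <- sim_config(generations = 3, founders = 500, cap = 2000)
  sim <- simulate_cross(cfg, g$map, g$markers, record = "final")
  model <- effect_size_model("II", 8e6, ve = 0.999, truncation = 0.05)
  pools <- truncation_select(sim$population, model)
  gmax <- max(genotype_at(sim$population, "II", 8e6))
  expect_true(all(genotype_at(pools$selected, "II", 8e6) == gmax))
  expect_equal(pools$selected$n, round(0.05 * sim$population$n))
  expect_equal(pools$control$n, pools$selected$n)
})

test_that("variance-consistent sigma^2 realises the requested Ve", {
  g <- small_genome()
  set.seed(44)
  cfg <- sim_config(generations = 2, founders = 2000, cap = 50000, progeny = 25)
  sim <- simulate_cross(cfg, g$map, g$markers, record = "final")
  pop <- sim$population
  geno <- genotype_at(pop, "II", 8e6)
  for (ve in c(0.05, 0.2, 0.5)) {
    model <- effect_size_model("II", 8e6, ve = ve)
    pools <- truncation_select(pop, model)
    realised <- pools$vl / (pools$vl + pools$sigma2)
    expect_lt(abs(realised - ve), 0.01)
    s <- geno + stats::rnorm(pop$n, 0, sqrt(pools$sigma2))
    expect_lt(abs(stats::var(geno) / stats::var(s) - ve), 0.01)
  }
})

test_that("the as-printed sigma^2 variant follows its formula", {
  m <- effect_size_model("I", 1e6, ve = 0.2, variant = "as-printed")
  expect_equal(displacement_variance(m, vl = 0.5), (1 - 0.2) / (0.2 * 0.5))
  expect_equal(displacement_variance(m, vl = 0.5), 8)
  mv <- effect_size_model("I", 1e6, ve = 0.2)
  expect_equal(displacement_variance(mv, vl = 0.5), 0.5 * (1 - 0.2) / 0.2)
  expect_error(displacement_variance(mv, vl = 0), "monomorphic")
})

test_that("pooled counts are binomial draws at the pool frequencies", {
  g <- small_genome()
  set.seed(45)
  # degenerate pools: all-B and all-A populations
  bb <- inbred_population(50, g$map, "B")
  aa <- inbred_population(50, g$map, "A")
  counts <- simulate_pool_counts(bb, aa, g$markers, coverage = 80)
  expect_true(all(counts$n3 == 80)) # high pool fixed for B
  expect_true(all(counts$n1 == 0))
  expect_true(all(counts$n2 == 80)) # control fixed for A
  expect_true(all(counts$n1 + counts$n3 == 80))
  expect_true(all(counts$n2 + counts$n4 == 80))
  # an F1 pool sits at frequency 0.5: the mean simulated frequency over
  # all autosomal markers matches within binomial error of the mean
  f1 <- founder_population(400, g$map, sex_ratio = 0.999)
  cc <- simulate_pool_counts(f1, f1, g$markers, coverage = 100)
  auto <- cc[cc$chrom != "X", ]
  fhat <- auto$n3 / (auto$n1 + auto$n3)
  se <- sqrt(0.25 / 100 / nrow(auto))
  expect_lt(abs(mean(fhat) - 0.5), 3 * se)
})

test_that("drive increases the element allele faster at higher penetrance", {
  g <- small_genome()
  set.seed(46)
  mk <- marker_grid(data.frame(chrom = "I", bp = 5e6), map = g$map)
  terminal <- function(s, reps = 20) {
    cfg <- sim_config(generations = 6, founders = 300, cap = 300,
                      drive = drive_element("I", 5e6, s = s))
    mean(replicate(reps, {
      sim <- simulate_cross(cfg, g$map, mk, record = "final")
      1 - sim$trajectory$freq_b[nrow(sim$trajectory)]
    }))
  }
  f0 <- terminal(0)
  f5 <- terminal(0.5)
  f10 <- terminal(1)
  expect_lt(abs(f0 - 0.5), 0.03)
  expect_gt(f5, f0 + 0.02)
  expect_gt(f10, f5)
})
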