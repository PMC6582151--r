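# Hand-computed oracle values are frozen as literals; tolerances are
# relative 1e-9 unless noted.

test_that("the modified G statistic matches hand-computed values", {
  expect_equal(g_statistic(50, 50, 50, 50, q = 0.5, C = 100), 0)
  expect_equal(g_statistic(50, 50, 50, 50, q = 0.5, C = 100,
                           variant = "as-printed-linear"), 0)
  expect_equal(g_statistic(60, 40, 40, 60, q = 0.4, C = 100),
               8.333333333333334, tolerance = 1e-9)
  expect_equal(g_statistic(60, 40, 40, 60, q = 0.4, C = 100,
                           variant = "as-printed-linear"),
               -0.4166666666666667, tolerance = 1e-9)
  expect_error(g_statistic(1, 1, 1, 1, q = 0, C = 10), "strictly in")
  expect_error(g_statistic(1, 1, 1, 1, q = 0.5, C = 0), "positive")
})

test_that("the squared G is invariant to swapping pools with q held fixed", {
  set.seed(51)
  n1 <- rpois(200, 50); n2 <- rpois(200, 50)
  n3 <- rpois(200, 50); n4 <- rpois(200, 50)
  q <- runif(200, 0.2, 0.8)
  expect_equal(
    g_statistic(n1, n2, n3, n4, q, 100),
    g_statistic(n2, n1, n4, n3, q, 100),
    tolerance = 1e-12
  )
  # the linear variant flips sign instead
  expect_equal(
    g_statistic(n1, n2, n3, n4, q, 100, variant = "as-printed-linear"),
    -g_statistic(n2, n1, n4, n3, q, 100, variant = "as-printed-linear"),
    tolerance = 1e-12
  )
})

test_that("q and coverage follow the stated conventions", {
  tab <- tibble::tibble(chrom = "I", pos = 1:3,
                        n1 = c(60, 60, 0), n3 = c(60, 60, 0),
                        n2 = c(40, 0, 40), n4 = c(60, 0, 0))
  est <- estimate_q_and_c(tab)
  expect_equal(est$q[1], 0.4)
  expect_equal(est$C[1], (120 + 100) / 2)
  expect_true(est$exclude[2]) # zero control depth
  expect_true(est$exclude[3]) # q = 1 and zero coverage in high pool
  expect_equal(estimate_q_and_c(tab, "min")$C[1], 100)
  expect_equal(estimate_q_and_c(tab, "control")$C[1], 100)
})

test_that("tri-cube smoothing matches hand-computed kernel weights", {
  # isolated marker: self-weight one
  expect_equal(tricube_smooth(5, 10, "I"), 5)
  # constant G is reproduced exactly (weights sum to one)
  expect_equal(tricube_smooth(rep(3, 7), seq(0, 6, 1), rep("I", 7)),
               rep(3, 7), tolerance = 1e-12)
  # two markers 6.25 cM apart: raw weights 1 and (1 - 0.5^3)^3
  gp <- tricube_smooth(c(10, 2), c(0, 6.25), c("I", "I"))
  expect_equal(gp[1], 6.790643274853801, tolerance = 1e-9)
  # markers at or beyond the half-width get zero weight
  gp2 <- tricube_smooth(c(10, 2), c(0, 12.5), c("I", "I"))
  expect_equal(gp2, c(10, 2))
  # different chromosomes never share a window
  gp3 <- tricube_smooth(c(10, 2), c(0, 0.1), c("I", "II"))
  expect_equal(gp3, c(10, 2))
  # unsorted input is handled and returned in input order
  set.seed(52)
  cm <- runif(50, 0, 50)
  g <- runif(50)
  ord <- sample(50)
  expect_equal(tricube_smooth(g, cm, rep("I", 50))[ord],
               tricube_smooth(g[ord], cm[ord], rep("I", 50)))
})

test_that("the robust log-normal fit recovers known parameters", {
  set.seed(53)
  x <- stats::rlnorm(10000, meanlog = 1, sdlog = 0.5)
  fit <- fit_null_lognormal(x)
  expect_lt(abs(fit$mu - 1), 0.03)
  expect_lt(abs(fit$sigma - 0.5), 0.03)
})

test_that("the null fit resists upper-tail contamination", {
  set.seed(54)
  x <- stats::rlnorm(10000, meanlog = 1, sdlog = 0.5)
  clean <- fit_null_lognormal(x)
  spiked <- x
  idx <- sample(10000, 500)
  spiked[idx] <- 100 * stats::median(x)
  robust <- fit_null_lognormal(spiked)
  expect_lt(abs(robust$mu - clean$mu), 0.05)
  # a mean/SD fit on the same data shifts far more
  expect_gt(abs(mean(log(spiked)) - mean(log(x))), 0.2)
})

test_that("degenerate and undersized null fits are rejected", {
  expect_error(fit_null_lognormal(rep(2, 500)), "degenerate")
  expect_error(fit_null_lognormal(stats::rlnorm(50)), "fewer than 100")
})

test_that("log-normal p-values match normal-CDF arithmetic", {
  null <- structure(list(mu = 0, sigma = 1), class = "lognormal_null")
  expect_equal(lognormal_pvalues(exp(0), null), 0.5)
  expect_equal(lognormal_pvalues(exp(2), null), 0.02275013194817922,
               tolerance = 1e-9)
  null2 <- structure(list(mu = 1.3, sigma = 0.4), class = "lognormal_null")
  expect_equal(lognormal_pvalues(exp(1.3), null2), 0.5)
  # p is strictly decreasing in G': rankings are exactly inverse
  set.seed(55)
  gp <- stats::rlnorm(500)
  p <- lognormal_pvalues(gp, null)
  expect_equal(order(p), order(-gp))
})

test_that("peak calling merges contiguous significant runs", {
  mk <- tibble::tibble(
    chrom = rep("I", 10), pos = 1:10 * 100,
    p = c(0.5, 1e-6, 1e-8, 1e-6, 0.5, 0.5, 1e-7, 1e-7, 0.5, 0.5)
  )
  peaks <- call_peaks(mk, alpha = 1e-5)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$pos, c(300, 700)) # min-p marker; leftmost on ties
  expect_equal(peaks$n_markers, c(3, 2))
  expect_equal(nrow(call_peaks(mk, alpha = 1e-10)), 0)
  one <- call_peaks(mk[1:5, ], alpha = 1e-5)
  expect_equal(nrow(one), 1)
  expect_equal(one$run_start, 200)
  expect_equal(one$run_end, 400)
})

test_that("run_scan localises a planted locus and is deterministic", {
  g <- small_genome()
  set.seed(56)
  cfg <- sim_config(generations = 6, founders = 500, cap = 5000)
  sim <- simulate_cross(cfg, g$map, g$markers, record = "final")
  causal <- list(chrom = "IV", bp = 9e6)
  pools <- truncation_select(
    sim$population,
    effect_size_model(causal$chrom, causal$bp, ve = 0.3)
  )
  counts <- simulate_pool_counts(pools$selected, pools$control, g$markers, 100)
  scan1 <- run_scan(counts, g$map)
  scan2 <- run_scan(counts, g$map)
  expect_identical(scan1$markers, scan2$markers)
  top <- scan1$markers[which.max(scan1$markers$G_smoothed), ]
  expect_equal(top$chrom, causal$chrom)
  d_cm <- abs(bp_to_cm(g$map, causal$chrom, top$pos) -
                bp_to_cm(g$map, causal$chrom, causal$bp))
  expect_lt(d_cm, 5)
  expect_s3_class(tidy(scan1), "tbl_df")
  expect_equal(glance(scan1)$n_markers, nrow(scan1$markers))
})

test_that("monomorphic-control markers are excluded from the scan", {
  g <- small_genome()
  set.seed(57)
  f1 <- founder_population(200, g$map)
  counts <- simulate_pool_counts(f1, f1, g$markers, coverage = 6)
  # low coverage: some markers will have q of exactly 0 or 1
  est <- estimate_q_and_c(counts)
  expect_gt(sum(est$exclude), 0)
  expect_message(scan <- run_scan(counts, g$map), "excluding")
  expect_equal(nrow(scan$markers), sum(!est$exclude))
  expect_true(all(scan$markers$q > 0 & scan$markers$q < 1))
})

test_that("nearest-rank CIs match quantile arithmetic", {
  expect_equal(nearest_rank_ci(1:1000), c(26, 975))
  expect_equal(nearest_rank_ci(rep(42, 50)), c(42, 42))
  expect_equal(nearest_rank_ci(1:10, level = 0.8), c(2, 9))
})
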