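test_that("probe filtering applies the presence threshold with >= at the boundary", {
  m <- matrix(rnorm(300), nrow = 3, ncol = 100,
              dimnames = list(c("p60", "p67", "pfull"), NULL))
  m[1, 1:40] <- NA # present in 60/100 < 2/3: removed
  m[2, 1:33] <- NA # present in 67/100 >= 2/3 (boundary via >=): kept
  expect_message(kept <- filter_probes(m), "removed 1 probe")
  expect_equal(rownames(kept), c("p67", "pfull"))
  expect_error(filter_probes(m[1, , drop = FALSE]), "all probes removed")
  m2 <- matrix(rnorm(30), 3)
  m2[1, 1] <- NA # 9/10 kept at default threshold
  expect_silent(expect_equal(nrow(filter_probes(m2)), 3))
  # exact boundary: 2 of 3 samples present with min_presence 2/3 is kept
  m3 <- matrix(c(1, NA, 2, 1, 2, 3), nrow = 2, byrow = TRUE)
  expect_equal(nrow(filter_probes(m3, 2 / 3)), 2)
})

test_that("LOD transform matches hand-computed values", {
  expect_equal(lod_from_r2(0, 100), 0)
  expect_equal(lod_from_r2(0.2, 100), 4.845500650402819, tolerance = 1e-9)
  # closed-form coincidence: -ln(0.01) = 2 ln 10, so n = 50 gives LOD 50
  expect_equal(lod_from_r2(0.99, 50), 50, tolerance = 1e-9)
  expect_error(lod_from_r2(1, 10), "\\[0, 1\\)")
  expect_error(lod_from_r2(0.5, 2), "at least 3")
  # strictly increasing in both arguments
  expect_true(all(diff(lod_from_r2(seq(0, 0.9, 0.1), 50)) > 0))
  expect_true(all(diff(lod_from_r2(0.3, c(10, 50, 200))) > 0))
})

test_that("row normalisation is idempotent and yields mean 0, variance 1", {
  set.seed(71)
  m <- matrix(rnorm(500, mean = 3, sd = 2), nrow = 10)
  m[1, 3] <- NA
  z <- normalize_rows(m)
  expect_equal(unname(rowMeans(z, na.rm = TRUE)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::var, na.rm = TRUE)), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(normalize_rows(z), z, tolerance = 1e-12)
  expect_error(normalize_rows(matrix(1, 2, 5)), "constant row")
})

test_that("eQTL LOD equals the transform of an independently computed correlation", {
  set.seed(72)
  n <- 60
  geno <- matrix(sample(c(-1, 1), 20 * n, replace = TRUE), nrow = 20)
  expr <- matrix(rnorm(30 * n), nrow = 30)
  expr[sample(length(expr), 50)] <- NA
  res <- map_eqtls(expr, geno)
  for (k in 1:100) {
    i <- sample(30, 1)
    j <- sample(20, 1)
    x <- expr[i, ]
    y <- geno[j, ]
    n_pair <- sum(!is.na(x) & !is.na(y))
    r <- manual_cor(x, y)
    expect_equal(res$lod[i, j], lod_from_r2(r^2, n_pair), tolerance = 1e-9)
  }
})

test_that("LOD is invariant to negating either vector and finds perfect probes", {
  set.seed(73)
  n <- 50
  geno <- matrix(sample(c(0, 1), 10 * n, replace = TRUE), nrow = 10)
  expr <- rbind(geno[4, ], -geno[7, ], rnorm(n))
  res <- map_eqtls(expr, geno)
  expect_equal(res$best$marker[1], "4")
  expect_equal(res$best$marker[2], "7") # negation does not change R^2
  expect_equal(res$lod[1, 4], max(res$lod), tolerance = 1e-9)
  expect_lt(res$best$lod[3], lod_from_r2(0.25, n)) # noise probe stays low
  resn <- map_eqtls(-expr, geno)
  expect_equal(res$lod, resn$lod, tolerance = 1e-9)
  expect_error(map_eqtls(expr[, 1:40], geno), "sample counts differ")
})

test_that("permutation FDR is deterministic and behaves on pure noise", {
  set.seed(74)
  expr <- matrix(rnorm(200 * 40), nrow = 200)
  geno <- matrix(sample(c(0, 1), 30 * 40, replace = TRUE), nrow = 30)
  set.seed(99)
  a <- permutation_fdr(expr, geno, n_perm = 20)
  set.seed(99)
  b <- permutation_fdr(expr, geno, n_perm = 20)
  expect_identical(a$cutoff, b$cutoff)
  expect_identical(a$curve, b$curve)
  # pure noise: FDR near 1 at low thresholds; no (or an extreme) cutoff
  low <- a$curve[a$curve$n_observed >= 20, ]
  expect_gt(stats::median(low$fdr), 0.5)
})

test_that("planted signals are recovered at the chosen FDR cutoff", {
  set.seed(75)
  n <- 100
  geno <- matrix(sample(c(0, 1), 40 * n, replace = TRUE), nrow = 40)
  planted_marker <- sample(40, 50, replace = TRUE)
  noise <- matrix(rnorm(950 * n), nrow = 950)
  signal <- t(vapply(planted_marker, function(j) {
    # genotype variance 0.25 + noise variance 0.25: R^2 about 0.5
    geno[j, ] + rnorm(n, 0, 0.5)
  }, numeric(n)))
  expr <- rbind(signal, noise)
  rownames(expr) <- c(paste0("hit", 1:50), paste0("null", 1:950))
  fdr <- permutation_fdr(expr, geno, n_perm = 30)
  expect_false(is.na(fdr$cutoff))
  expect_lte(fdr$fdr_at_cutoff, 0.05)
  res <- map_eqtls(expr, geno, cutoff = fdr$cutoff)
  hits <- res$best[res$best$significant, ]
  expect_gte(sum(grepl("^hit", hits$probe)), 45)
  # and the best marker is the planted one for recovered probes
  rec <- hits[grepl("^hit", hits$probe), ]
  idx <- as.integer(sub("hit", "", rec$probe))
  expect_gt(mean(rec$marker == as.character(planted_marker[idx])), 0.9)
})

test_that("matrix TSV reader round-trips", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(as.data.frame(m), rownames = "id"), path)
  back <- read_matrix_tsv(path)
  expect_equal(back, m, tolerance = 1e-12)
})
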