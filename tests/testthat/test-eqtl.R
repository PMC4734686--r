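test_that("marker regression matches a brute-force two-model fit", {
  set.seed(31)
  g <- simulate_ri_genotypes(sim_config(seed = 31, n_strains = 20,
                                        n_chrom = 2,
                                        markers_per_chrom = 8))
  y <- rnorm(20)
  names(y) <- rownames(g$calls)
  sc <- marker_regression(y, g)
  x <- code_genotypes(g)
  for (j in seq_len(ncol(x))) {
    if (is.na(sc$lrs[j])) next
    fit <- lm(y ~ x[, j])
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(residuals(fit)^2)
    expect_equal(sc$lrs[j], 20 * log(rss0 / rss1), tolerance = 1e-9)
    expect_equal(sc$additive[j], unname(coef(fit)[2]), tolerance = 1e-9)
  }
})

test_that("degenerate traits and markers are handled explicitly", {
  g <- make_geno(rbind(c(1, 1), c(-1, 1), c(1, 1), c(-1, 1)))
  y <- c(S01 = 2, S02 = 2, S03 = 2, S04 = 2)
  sc <- marker_regression(y, g)
  expect_equal(sc$lrs, c(0, 0))                 # constant trait

  y2 <- c(S01 = 1, S02 = 2, S03 = 3, S04 = 4)
  sc2 <- marker_regression(y2, g)
  expect_true(is.na(sc2$lrs[2]))                # monomorphic marker
  expect_false(is.na(sc2$lrs[1]))

  # perfect fit hits the LOD cap with a flag
  y3 <- c(S01 = 1, S02 = -1, S03 = 1, S04 = -1)
  sc3 <- marker_regression(y3, g, lod_cap = 50)
  expect_equal(sc3$lod[1], 50)
  expect_true(sc3$capped[1])
})

test_that("additive effect is half the class-mean difference, D positive", {
  g <- make_geno(cbind(c(1, 1, 1, -1, -1, -1)))
  y <- c(S01 = 5, S02 = 5, S03 = 5, S04 = 1, S05 = 1, S06 = 1)
  sc <- marker_regression(y, g)
  expect_equal(sc$additive[1], 2)               # class means differ by 4
  expect_gt(sc$additive[1], 0)                  # D class is higher
})

test_that("the scan is invariant to affine transforms of the trait", {
  set.seed(32)
  g <- simulate_ri_genotypes(sim_config(seed = 32, n_strains = 25,
                                        n_chrom = 1,
                                        markers_per_chrom = 10))
  y <- rnorm(25); names(y) <- rownames(g$calls)
  a <- marker_regression(y, g)
  b <- marker_regression(-2.5 * y + 7, g)
  expect_equal(a$lrs, b$lrs, tolerance = 1e-9)
})

test_that("LRS/LOD conversion follows LOD = LRS / (2 ln 10)", {
  expect_equal(lrs_to_lod(0), 0)
  expect_equal(lrs_to_lod(30.9), 6.70, tolerance = 0.02)
  expect_equal(lrs_to_lod(65.5), 14.21, tolerance = 0.02)
  expect_equal(lod_to_lrs(lrs_to_lod(12.3)), 12.3)
  expect_error(lrs_to_lod(-1), ">= 0")
})

test_that("permutation thresholds are deterministic, ordered, and match a brute-force oracle", {
  g <- simulate_ri_genotypes(sim_config(seed = 33, n_strains = 18,
                                        n_chrom = 2,
                                        markers_per_chrom = 6))
  y <- rnorm(18); names(y) <- rownames(g$calls)

  t1 <- permutation_threshold(y, g, n_perm = 100, seed = 9)
  t2 <- permutation_threshold(y, g, n_perm = 100, seed = 9)
  expect_identical(t1, t2)

  both <- permutation_threshold(y, g, n_perm = 100,
                                alpha = c(0.05, 0.63), seed = 9)
  expect_gte(both[["0.05"]], both[["0.63"]])

  # constant trait: all permutation maxima are zero
  y0 <- rep(1, 18); names(y0) <- rownames(g$calls)
  expect_equal(permutation_threshold(y0, g, n_perm = 50, seed = 1), 0)

  # oracle: regenerate the same permutations and scan each one
  n_perm <- 60
  set.seed(9)
  perms <- matrix(0L, 18, n_perm)
  for (i in seq_len(n_perm)) perms[, i] <- sample.int(18)
  maxlod <- vapply(seq_len(n_perm), function(i) {
    yy <- y[perms[, i]]
    names(yy) <- rownames(g$calls)
    max(marker_regression(yy, g)$lod, na.rm = TRUE)
  }, numeric(1))
  oracle <- quantile(maxlod, 0.95, names = FALSE, type = 7)
  expect_equal(permutation_threshold(y, g, n_perm = n_perm, seed = 9),
               oracle, tolerance = 1e-9)
})

test_that("LOD support intervals follow the midpoint-extension rule", {
  # single spike: interval reaches the midpoints to adjacent markers
  sc <- make_scan(c(0.2, 0.3, 5, 0.1, 0.2), mb = c(10, 20, 30, 40, 50))
  ci <- lod_support_interval(sc)
  expect_equal(ci$left_mb, 25)
  expect_equal(ci$right_mb, 35)

  # flat curve: whole chromosome
  flat <- make_scan(rep(1.2, 5), mb = c(10, 20, 30, 40, 50))
  ci2 <- lod_support_interval(flat)
  expect_equal(c(ci2$left_mb, ci2$right_mb), c(10, 50))

  # infinite drop: whole chromosome regardless of shape
  ci3 <- lod_support_interval(sc, drop = Inf)
  expect_equal(c(ci3$left_mb, ci3$right_mb), c(10, 50))

  # the peak is always inside the interval
  set.seed(34)
  for (i in 1:10) {
    s <- make_scan(runif(8, 0, 6))
    pk <- find_peak(s)
    ci <- lod_support_interval(s)
    expect_true(ci$left_mb <= pk$mb && pk$mb <= ci$right_mb)
  }
})

test_that("cis/trans classification uses an inclusive window", {
  expect_equal(classify_cis_trans("9", 78, "9", 78), "cis")
  expect_equal(classify_cis_trans("2", 78, "9", 78), "trans")
  expect_equal(classify_cis_trans("9", 88, "9", 78, window_mb = 10), "cis")
  expect_equal(classify_cis_trans("9", 88.01, "9", 78, window_mb = 10),
               "trans")
  expect_true(is.na(classify_cis_trans("9", 78, NA, NA)))
})

test_that("map_eqtl recovers a planted cis effect end to end", {
  cfg <- sim_config(seed = 35, n_strains = 60, n_probes = 3,
                    effects = data.frame(probe = "probe001",
                                         marker = "c3m10", effect = 0.8),
                    var_strain = 0.05, var_resid = 0.05)
  g <- simulate_ri_genotypes(cfg)
  se <- simulate_expression(g, cfg)
  res <- map_eqtl(se$expr, g, n_perm = 200, seed = 35)
  hit <- res$peaks[res$peaks$probe == "probe001", ]
  expect_true(hit$significant)
  expect_equal(hit$class, "cis")
  expect_equal(hit$peak_chr, "3")
  truth_mb <- g$map$mb[g$map$marker == "c3m10"]
  expect_true(hit$ci_left_mb <= truth_mb && truth_mb <= hit$ci_right_mb)
  expect_gt(hit$additive, 0)
})
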