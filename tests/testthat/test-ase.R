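test_that("allelic ratio is reference reads over total reads", {
  expect_equal(allelic_ratio(317, 699), 317 / 1016)
  expect_equal(round(allelic_ratio(317, 699), 2), 0.31)
  expect_equal(round(allelic_ratio(1098, 720), 2), 0.60)
  for (k in c(1, 7, 500)) expect_equal(allelic_ratio(k, k), 0.5)
  expect_true(is.na(allelic_ratio(0, 0)))
})

test_that("IQR outlier fences use interpolated quartiles", {
  expect_false(any(iqr_outlier_mask(rep(0.43, 6))))      # IQR = 0
  m <- iqr_outlier_mask(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.9))
  expect_equal(which(m), 6L)                             # fences collapse
  expect_false(any(iqr_outlier_mask(c(0.40, 0.45, 0.50,
                                      0.55, 0.60, 0.62))))
  # hand-computed type-7 fences: Q1 = 0.4625, Q3 = 0.5875, IQR = 0.125
  # -> [0.275, 0.775]; 0.25 is below the lower fence
  m2 <- iqr_outlier_mask(c(0.25, 0.45, 0.50, 0.55, 0.60, 0.62))
  expect_true(m2[1])
  expect_equal(sum(m2), 1L)
})

test_that("merging sums counts over concordant replicates only", {
  expect_equal(merge_concordant(10, 20, FALSE), list(ref = 10, alt = 20))
  expect_equal(merge_concordant(c(10, 20), c(10, 20), c(FALSE, FALSE)),
               list(ref = 30, alt = 30))
  expect_equal(merge_concordant(c(10, 20, 90), c(10, 20, 10),
                                c(FALSE, FALSE, TRUE)),
               list(ref = 30, alt = 30))
  expect_error(merge_concordant(1, 1, TRUE), "all replicates")
})

test_that("chi-square imbalance test reproduces worked values", {
  t1 <- chi_square_imbalance(86, 161)
  expect_equal(signif(t1$p_value, 3), 1.82e-6)
  t2 <- chi_square_imbalance(3902, 4007)
  expect_equal(signif(t2$p_value, 3), 0.238)
  t3 <- chi_square_imbalance(250, 250)
  expect_equal(t3$chi2, 0)
  expect_equal(t3$p_value, 1)
})

test_that("imbalance p decreases as the ratio departs from one half", {
  refs <- seq(100, 180, by = 10)
  p <- chi_square_imbalance(refs, 200 - refs)$p_value
  expect_true(all(diff(p) < 0))
})

test_that("BH q-values equal a hand-rolled step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))

  step_up <- function(p) {      # independent textbook implementation
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(41)
  for (i in 1:10) {
    p <- runif(4)
    expect_equal(bh_fdr(p), step_up(p))
  }
})

test_that("allelic fold difference and the strict gene-level filters", {
  expect_equal(fold_difference(0.5), 1)
  expect_equal(fold_difference(5 / 9), 1.25)   # boundary: NOT > 1.25
  expect_gt(fold_difference(317 / 1016), 2.2)  # strong imbalance

  mk <- function(ref, alt, gene = "g1") {
    allele_counts(data.frame(gene = gene, chrom = "1", pos = 100L,
                             ref_base = "A", alt_base = "G",
                             replicate_id = sprintf("r%d", seq_along(ref)),
                             ref_count = ref, alt_count = alt,
                             tissue = "liver"))
  }
  # balanced counts: fold = 1, never imbalanced however large the depth
  bal <- ase_call(mk(rep(5000L, 6), rep(5000L, 6)))
  expect_false(bal$gene$imbalanced)

  # strong imbalance (ratio 0.312): q tiny, fold > 1.25 -> imbalanced
  imb <- ase_call(mk(rep(317L, 6), rep(699L, 6)))
  expect_true(imb$gene$imbalanced)
  expect_equal(round(imb$snp$allelic_ratio, 2), 0.31)

  # ratio 5/9: fold exactly 1.25 fails the strict fold filter
  edge <- ase_call(mk(rep(5000L, 6), rep(4000L, 6)))
  expect_false(edge$gene$imbalanced)
  expect_lt(edge$snp$q_value, 0.1)             # fails on fold alone
})

test_that("caller drops zero-coverage and low-depth SNPs with a record", {
  df <- allele_counts(data.frame(
    gene = rep(c("g1", "g2"), each = 2), chrom = "1",
    pos = rep(c(100L, 200L), each = 2),
    ref_base = "A", alt_base = "G",
    replicate_id = rep(c("r1", "r2"), 2),
    ref_count = c(40L, 42L, 2L, 1L), alt_count = c(38L, 41L, 1L, 2L),
    tissue = "liver"))
  out <- ase_call(df, min_depth = 10)
  expect_equal(nrow(out$snp), 1L)
  expect_equal(out$dropped$reason, "low_depth")
})

test_that("merging replicates with identical ratios leaves the ratio fixed", {
  r1 <- allelic_ratio(30, 70)
  m <- merge_concordant(c(30, 60, 90), c(70, 140, 210), rep(FALSE, 3))
  expect_equal(m$ref / (m$ref + m$alt), r1)
})

test_that("q-values are controlled on a simulated null (theta = 0.5)", {
  cfg <- sim_config(seed = 42, n_ase_genes = 1000, theta = 0.5)
  calls <- ase_call(simulate_ase_counts(cfg)$counts)
  expect_lte(mean(calls$snp$q_value < 0.1), 0.12)
})
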