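test_that("pearson_with_p matches direct formulas and cor.test", {
  set.seed(51)
  x <- rnorm(10); y <- rnorm(10)
  pr <- pearson_with_p(x, y, tail = "two.sided")
  # brute-force covariance / (sd sd)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_direct, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(pr$p_value, ct$p.value, tolerance = 1e-12)
  one <- pearson_with_p(x, y, tail = "one.sided")
  expect_equal(one$p_value, ct$p.value / 2, tolerance = 1e-12)

  expect_equal(pearson_with_p(x, x)$r, 1)
  # p-values are invariant to affine transforms of either series
  pr2 <- pearson_with_p(3 * x - 1, -2 * y + 5, tail = "two.sided")
  expect_equal(pr2$p_value, pr$p_value, tolerance = 1e-12)
  # degenerate input: zero variance is skipped, not guessed
  expect_true(is.na(pearson_with_p(rep(1, 10), y)$r))
})

test_that("named series are aligned on common strains", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  y <- c(d = 8, c = 6, b = 4, a = 2, z = 99)
  pr <- pearson_with_p(x, y)
  expect_equal(pr$n, 4L)
  expect_equal(pr$r, 1)
})

test_that("partial correlation equals the single-covariate closed form", {
  set.seed(52)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    pc <- partial_correlation(x, y, cbind(z))
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$r, closed, tolerance = 1e-10)
    expect_equal(pc$df, 27L)
  }
})

test_that("partial correlation degenerates gracefully", {
  set.seed(53)
  x <- rnorm(25); y <- rnorm(25); z <- rnorm(25)
  # empty covariate set: exactly the plain correlation
  expect_equal(partial_correlation(x, y, NULL)$r,
               pearson_with_p(x, y)$r)
  # a series equal to a covariate has nothing left to correlate
  pc <- partial_correlation(x, z, cbind(z))
  expect_equal(pc$r, 0)
  expect_equal(pc$p_value, 1)
  # collinear covariates are dropped, df reflects the rank
  expect_message(pc2 <- partial_correlation(x, y, cbind(z, 2 * z)),
                 "collinear")
  expect_equal(pc2$df, 25L - 2L - 1L)
  expect_equal(pc2$r, partial_correlation(x, y, cbind(z))$r,
               tolerance = 1e-12)
})

test_that("covariates orthogonal to both series leave r unchanged", {
  n <- 40
  x <- rnorm(n); y <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x + y))        # orthogonalized covariate
  pc <- partial_correlation(x, y, cbind(z))
  expect_equal(pc$r, cor(x, y), tolerance = 1e-10)
})

test_that("module PC1 matches an independent eigen decomposition", {
  set.seed(54)
  vals <- matrix(rnorm(8 * 30), 8, 30)
  e <- make_expr(vals)
  m <- module_pc1(e, rownames(e$values))
  # oracle: eigenvalues of the correlation matrix via svd
  s <- scale(t(vals))
  ev <- svd(s)$d^2
  expect_equal(m$variance_explained, ev[1] / sum(ev), tolerance = 1e-9)
  expect_gte(m$variance_explained, 1 / 8)
  expect_lte(m$variance_explained, 1)
  # orientation: the signature tracks the members on average
  expect_gt(mean(cor(m$signature, s)), 0)

  # two identical probes: PC1 is everything
  twin <- make_expr(rbind(vals[1, ], vals[1, ]))
  expect_equal(module_pc1(twin, c("p01", "p02"))$variance_explained, 1)
})

test_that("PC1 variance explained follows a one-factor model", {
  set.seed(55)
  nstr <- 300; m <- 8; lambda <- 1; sigma <- 0.5
  f <- rnorm(nstr)
  vals <- t(sapply(seq_len(m), function(i) lambda * f +
                                 rnorm(nstr, 0, sigma)))
  e <- make_expr(vals)
  rho <- lambda^2 / (lambda^2 + sigma^2)
  expected <- (1 + (m - 1) * rho) / m
  expect_equal(module_pc1(e, rownames(e$values))$variance_explained,
               expected, tolerance = 0.05)
})

test_that("network edges honour the magnitude thresholds with sign", {
  set.seed(56)
  base <- rnorm(30)
  vals <- rbind(base, base + rnorm(30, 0, 0.01), -base + rnorm(30, 0, 0.3),
                rnorm(30))
  e <- make_expr(vals)
  net <- build_network(e, rownames(e$values))
  edge12 <- net[net$a == "p01" & net$b == "p02", ]
  expect_equal(edge12$class, "strong")
  expect_equal(edge12$sign, "+")
  edge13 <- net[net$a == "p01" & net$b == "p03", ]
  expect_equal(edge13$sign, "-")
  # impossible threshold: no edges at all
  expect_equal(nrow(build_network(e, rownames(e$values),
                                  edge_threshold = 1)), 0L)
})

test_that("null genes produce roughly the nominal number of edges", {
  set.seed(57)
  vals <- matrix(rnorm(20 * 60), 20, 60)
  e <- make_expr(vals)
  net <- build_network(e, rownames(e$values))
  # P(|r| > 0.3 | null, n = 60) ~ 0.02 -> ~4 of 190 pairs
  expect_lte(nrow(net), 15L)
})

test_that("top correlates rank by |r| with deterministic ties", {
  set.seed(58)
  vals <- matrix(rnorm(50 * 25), 50, 25)
  e <- make_expr(vals)
  top <- top_correlates("p01", e)
  expect_equal(top$probe[1], "p01")
  expect_equal(top$r[1], 1)
  expect_equal(nrow(top), 50L)              # n larger than probe count
  # oracle: full sort on brute-force correlations
  r <- apply(vals, 1, function(v) cor(v, vals[1, ]))
  probes <- rownames(e$values)
  ord <- order(-abs(r), probes)
  expect_equal(top$probe, probes[ord])

  top3 <- top_correlates("p01", e, n = 3)
  expect_equal(nrow(top3), 3L)
})

test_that("partial-correlate selection separates true partners from linkage", {
  set.seed(59)
  n <- 50
  g <- sample(c(-1, 1), n, replace = TRUE)       # controlled locus
  s <- rnorm(n)                                  # shared biology
  vals <- rbind(target = s + g,
                partner = s + rnorm(n, 0, 0.3),  # shares s, not g
                decoy = g + rnorm(n, 0, 0.3),    # correlated via g only
                noise = rnorm(n))
  colnames(vals) <- sprintf("S%02d", 1:n)
  e <- make_expr(vals)
  geno <- make_geno(cbind(g, rnorm(n)))          # marker 1 = the locus
  lit <- data.frame(symbol = c("PARTNER", "DECOY", "NOISE"),
                    r = c(0.9, 0.9, 0.9))
  sel <- select_partial_correlates(e, "target", geno, "m01", lit,
                                   p_max = 0.001, lit_min = 0.5)
  expect_true("partner" %in% sel$probe)
  expect_false("decoy" %in% sel$probe)

  # empty literature table: nothing passes
  none <- select_partial_correlates(e, "target", geno, "m01", NULL)
  expect_equal(nrow(none), 0L)
  expect_gte(attr(none, "n_missing_literature"), 1L)

  # fully permissive thresholds return every testable probe by |r|
  all_probes <- select_partial_correlates(e, "target", geno, "m01",
                                          data.frame(symbol =
                                            c("PARTNER", "DECOY", "NOISE"),
                                            r = 0.99),
                                          p_max = 1 + 1e-9, lit_min = -1)
  expect_equal(sort(all_probes$probe), c("decoy", "noise", "partner"))
  expect_equal(abs(all_probes$r[1]), max(abs(all_probes$r)))
})
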