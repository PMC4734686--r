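# Single-marker genome scans with permutation thresholds, 1.5-LOD support
# intervals and cis/trans classification.
#
# For a densely genotyped homozygous RI panel, single-marker regression
# coincides with interval mapping at the markers themselves, and peaks are
# reported at markers, so no between-marker imputation is performed.

TWO_LN10 <- 2 * log(10)

#' Convert a likelihood-ratio statistic to a LOD score
#'
#' `LOD = LRS / (2 ln 10) ~ LRS / 4.60517`.
#'
#' @param lrs Nonnegative likelihood-ratio statistic(s).
#' @return LOD score(s).
#' @export
lrs_to_lod <- function(lrs) {
  if (any(lrs < 0, na.rm = TRUE)) stop("LRS must be >= 0")
  lrs / TWO_LN10
}

#' Convert a LOD score to a likelihood-ratio statistic
#' @param lod Nonnegative LOD score(s).
#' @return LRS value(s).
#' @export
lod_to_lrs <- function(lod) {
  if (any(lod < 0, na.rm = TRUE)) stop("LOD must be >= 0")
  lod * TWO_LN10
}

#' Single-marker regression genome scan
#'
#' Least-squares fit of the trait on genotype coded B = -1 / D = +1 at each
#' marker.  The statistic is `LRS = n ln(RSS0 / RSS1)` with `RSS0` the
#' residual sum of squares about the mean and `RSS1` about the fit;
#' `LOD = LRS / (2 ln 10)`.  The additive effect is the regression slope:
#' half the D-minus-B class-mean difference, positive when the D allele
#' raises the trait.
#'
#' Markers with fewer than 3 usable strains, or monomorphic among them,
#' get missing statistics (never zero).  A perfect fit (`RSS1 = 0`) is
#' reported at the configured LOD cap with `capped = TRUE`.
#'
#' @param trait Named numeric vector (strain -> value).
#' @param geno A [geno_matrix()].
#' @param het How to code heterozygous calls; see [code_genotypes()].
#' @param lod_cap LOD reported for a perfect fit (default 50).
#' @return Data frame of class `qtl_scan`: `marker`, `chr`, `mb`, `n`,
#'   `lrs`, `lod`, `additive`, `capped`.
#' @export
marker_regression <- function(trait, geno, het = c("drop", "zero"),
                              lod_cap = 50) {
  het <- match.arg(het)
  x <- code_genotypes(geno, het)
  if (is.null(names(trait))) {
    if (length(trait) != nrow(x))
      stop("unnamed trait must have one value per strain")
    names(trait) <- rownames(x)
  }
  common <- intersect(rownames(x), names(trait))
  if (!length(common)) stop("no strains shared between trait and genotypes")
  x <- x[common, , drop = FALSE]
  y <- as.numeric(trait[common])

  m <- ncol(x)
  n_used <- integer(m); lrs <- rep(NA_real_, m)
  add <- rep(NA_real_, m); capped <- logical(m)
  for (j in seq_len(m)) {
    use <- !is.na(y) & !is.na(x[, j])
    n <- sum(use)
    n_used[j] <- n
    if (n < 3L) next
    yy <- y[use]; xx <- x[use, j]
    my <- mean(yy); mx <- mean(xx)
    rss0 <- sum((yy - my)^2)
    if (rss0 <= 0) { lrs[j] <- 0; add[j] <- 0; next }
    sxx <- sum((xx - mx)^2)
    if (sxx <= 0) next                       # monomorphic: undefined
    sxy <- sum((xx - mx) * (yy - my))
    b <- sxy / sxx
    rss1 <- rss0 - sxy^2 / sxx
    add[j] <- b
    if (rss1 <= rss0 * 1e-12) {              # perfect fit guard
      lrs[j] <- lod_cap * TWO_LN10
      capped[j] <- TRUE
    } else {
      lrs[j] <- n * log(rss0 / rss1)
    }
  }
  out <- data.frame(marker = geno$map$marker, chr = geno$map$chr,
                    mb = geno$map$mb, n = n_used, lrs = lrs,
                    lod = lrs / TWO_LN10, additive = add, capped = capped)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Peak of a genome scan
#'
#' Highest-LOD marker; ties are broken by the lowest genomic coordinate
#' (chromosome order of the map, then Mb) so peaks are deterministic.
#'
#' @param scan A `qtl_scan` from [marker_regression()].
#' @return The peak row of the scan (single-row data frame).
#' @export
find_peak <- function(scan) {
  ok <- !is.na(scan$lod)
  if (!any(ok)) stop("scan has no usable markers")
  sub <- scan[ok, , drop = FALSE]
  chr_rank <- match(sub$chr, unique(scan$chr))
  best <- which(sub$lod == max(sub$lod))
  best <- best[order(chr_rank[best], sub$mb[best])][1L]
  sub[best, , drop = FALSE]
}

#' Permutation-based genome-wide significance threshold
#'
#' Strain labels of the trait are permuted `n_perm` times; the threshold is
#' the empirical `1 - alpha` quantile (linear interpolation) of the
#' genome-wide maximum LOD over permutations.  Deterministic under a fixed
#' seed.  When the usable genotype matrix is complete the scan is
#' vectorised across permutations; otherwise each permutation is scanned
#' marker by marker.
#'
#' @param trait Named numeric vector (strain -> value).
#' @param geno A [geno_matrix()].
#' @param n_perm Number of permutations (genome-wide empirical P-values
#'   conventionally use 5000 or more).
#' @param alpha Genome-wide type-I error level(s); 0.05 for the
#'   significant and 0.63 (by convention, about one false positive per
#'   scan) for the suggestive threshold.
#' @param seed Optional integer seed.
#' @param het Heterozygote handling; see [code_genotypes()].
#' @return Threshold LOD (named vector if `length(alpha) > 1`).
#' @export
permutation_threshold <- function(trait, geno, n_perm = 5000, alpha = 0.05,
                                  seed = NULL, het = c("drop", "zero")) {
  het <- match.arg(het)
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  x <- code_genotypes(geno, het)
  if (is.null(names(trait))) names(trait) <- rownames(x)
  common <- intersect(rownames(x), names(trait))
  y <- as.numeric(trait[common])
  x <- x[common, , drop = FALSE]
  usable <- !is.na(y)
  y <- y[usable]; x <- x[usable, , drop = FALSE]
  n <- length(y)
  perms <- matrix(0L, n, n_perm)
  for (i in seq_len(n_perm)) perms[, i] <- sample.int(n)

  if (n >= 3L && stats::sd(y) > 0 && !anyNA(x)) {
    sds <- apply(x, 2L, stats::sd)
    xs <- scale(x[, sds > 0, drop = FALSE])
    ys <- as.vector(scale(y))
    if (ncol(xs) == 0L) {
      maxlod <- rep(0, n_perm)
    } else {
      yp <- matrix(ys[perms], n, n_perm)
      r <- crossprod(xs, yp) / (n - 1)
      r2 <- pmin(r * r, 1 - 1e-12)
      lod <- -n * log1p(-r2) / TWO_LN10
      maxlod <- apply(lod, 2L, max)
    }
  } else if (n >= 3L && stats::sd(y) > 0) {
    sub <- geno_subset_strains(geno, common[usable])
    maxlod <- vapply(seq_len(n_perm), function(i) {
      yy <- stats::setNames(y[perms[, i]], rownames(sub$calls))
      sc <- marker_regression(yy, sub, het = het)
      if (all(is.na(sc$lod))) 0 else max(sc$lod, na.rm = TRUE)
    }, numeric(1L))
  } else {
    maxlod <- rep(0, n_perm)
  }
  thr <- stats::quantile(maxlod, 1 - alpha, names = FALSE, type = 7)
  if (length(alpha) > 1L) names(thr) <- as.character(alpha)
  thr
}

geno_subset_strains <- function(geno, keep) {
  out <- geno_matrix(geno$calls[keep, , drop = FALSE], geno$map)
  attr(out, "metadata") <- attr(geno, "metadata")
  out
}

#' LOD support interval around a peak
#'
#' Widest contiguous marker span around the peak on its chromosome where
#' `LOD >= peak - drop`, extended half-way to the first excluded flanking
#' marker and truncated at the chromosome ends.  With `drop = 1.5` this is
#' the conventional 1.5-LOD confidence interval.
#'
#' @param scan A `qtl_scan`.
#' @param peak Optional peak row (defaults to [find_peak()]).
#' @param drop LOD drop defining the interval (default 1.5).
#' @return List with `chr`, `left_mb`, `right_mb`.
#' @export
lod_support_interval <- function(scan, peak = NULL, drop = 1.5) {
  if (is.null(peak)) peak <- find_peak(scan)
  sub <- scan[scan$chr == peak$chr & !is.na(scan$lod), , drop = FALSE]
  sub <- sub[order(sub$mb), , drop = FALSE]
  i0 <- which(sub$marker == peak$marker)
  thr <- peak$lod - drop
  l <- i0
  while (l > 1L && sub$lod[l - 1L] >= thr) l <- l - 1L
  r <- i0
  while (r < nrow(sub) && sub$lod[r + 1L] >= thr) r <- r + 1L
  left_mb <- if (l == 1L) sub$mb[1L] else (sub$mb[l - 1L] + sub$mb[l]) / 2
  right_mb <- if (r == nrow(sub)) sub$mb[nrow(sub)] else
    (sub$mb[r] + sub$mb[r + 1L]) / 2
  list(chr = peak$chr, left_mb = left_mb, right_mb = right_mb)
}

#' Classify an eQTL peak as cis (local) or trans (distant)
#'
#' Cis if and only if the peak lies on the gene's chromosome within
#' `window_mb` of the gene (inclusive boundary).
#'
#' @param peak_chr,peak_mb Peak location.
#' @param gene_chr,gene_mb Gene location; `NA` returns `NA` (no
#'   classification without an annotated gene position).
#' @param window_mb Cis window in Mb (default 10).
#' @return `"cis"`, `"trans"`, or `NA_character_`.
#' @export
classify_cis_trans <- function(peak_chr, peak_mb, gene_chr, gene_mb,
                               window_mb = 10) {
  ifelse(is.na(gene_chr) | is.na(gene_mb), NA_character_,
         ifelse(as.character(peak_chr) == as.character(gene_chr) &
                  abs(peak_mb - gene_mb) <= window_mb, "cis", "trans"))
}

#' Map eQTL for every probe of an expression matrix
#'
#' Runs [marker_regression()], [permutation_threshold()],
#' [lod_support_interval()] and [classify_cis_trans()] per probe.
#'
#' @param expr An [expr_matrix()].
#' @param geno A [geno_matrix()].
#' @param n_perm,alpha,alpha_suggestive Permutation settings.
#' @param cis_window_mb Cis window in Mb.
#' @param drop LOD-drop for the support interval.
#' @param seed Optional integer seed (per-probe seeds are derived from it).
#' @param het Heterozygote handling.
#' @return List with `peaks` (one row per probe: peak marker/location,
#'   LOD, thresholds, interval, class, additive effect) and `scans` (named
#'   list of `qtl_scan` objects).
#' @export
map_eqtl <- function(expr, geno, n_perm = 1000, alpha = 0.05,
                     alpha_suggestive = 0.63, cis_window_mb = 10,
                     drop = 1.5, seed = NULL, het = c("drop", "zero")) {
  het <- match.arg(het)
  stopifnot(inherits(expr, "expr_matrix"))
  probes <- rownames(expr$values)
  scans <- vector("list", length(probes)); names(scans) <- probes
  rows <- vector("list", length(probes))
  for (i in seq_along(probes)) {
    y <- expr$values[i, ]
    sc <- marker_regression(y, geno, het = het)
    scans[[i]] <- sc
    pk <- find_peak(sc)
    thr <- permutation_threshold(y, geno, n_perm = n_perm,
                                 alpha = c(alpha, alpha_suggestive),
                                 seed = if (is.null(seed)) NULL else
                                   seed + i, het = het)
    ci <- lod_support_interval(sc, pk, drop = drop)
    ann <- expr$annotation[i, ]
    rows[[i]] <- data.frame(
      probe = probes[i], peak_marker = pk$marker, peak_chr = pk$chr,
      peak_mb = pk$mb, peak_lod = pk$lod, additive = pk$additive,
      threshold_lod = unname(thr[1L]), suggestive_lod = unname(thr[2L]),
      significant = pk$lod >= thr[1L],
      ci_left_mb = ci$left_mb, ci_right_mb = ci$right_mb,
      class = classify_cis_trans(pk$chr, pk$mb, ann$chr, ann$mb,
                                 cis_window_mb),
      n_permutations = n_perm)
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  list(peaks = peaks, scans = scans)
}
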