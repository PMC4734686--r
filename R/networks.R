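# Correlation and partial-correlation coexpression analysis.
#
# p-values use the t transform t = r sqrt(df / (1 - r^2)).  The one-sided
# default reports the upper-tail probability of |t| (half the two-sided
# p), matching how strain-panel correlation databases pair r with p; the
# two-sided convention is available everywhere via `tail`.

cor_p_from_r <- function(r, df, tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, 0))
  p <- stats::pt(t, df, lower.tail = FALSE)
  if (tail == "two.sided") p <- 2 * p
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Pearson correlation with p-value
#'
#' Sample Pearson correlation over pairwise-complete observations with a
#' Student-t p-value on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors; if both are named, they are aligned on
#'   their common names.
#' @param tail `"one.sided"` (default; upper tail of |t|) or
#'   `"two.sided"`.
#' @return List with `r`, `n`, `p_value` (all `NA` if fewer than 3
#'   complete pairs or either series has zero variance).
#' @export
pearson_with_p <- function(x, y, tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  use <- !is.na(x) & !is.na(y)
  n <- sum(use)
  if (n < 3L) return(list(r = NA_real_, n = n, p_value = NA_real_))
  xx <- x[use]; yy <- y[use]
  if (stats::sd(xx) == 0 || stats::sd(yy) == 0)
    return(list(r = NA_real_, n = n, p_value = NA_real_))
  r <- stats::cor(xx, yy)
  list(r = r, n = n, p_value = cor_p_from_r(r, n - 2, tail))
}

#' Partial correlation controlling for covariates
#'
#' Regresses `x` and `y` each on the covariates (with intercept) and
#' correlates the residuals; p-value on `n - 2 - k` degrees of freedom
#' where `k` is the number of linearly independent covariates.  Collinear
#' covariate columns are dropped (with a message).  An empty covariate set
#' reduces exactly to [pearson_with_p()].
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix (rows = observations) or `NULL`;
#'   typically coded genotypes at control markers.
#' @param tail p-value convention, as in [pearson_with_p()].
#' @return List with `r`, `n`, `df`, `p_value`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    out <- pearson_with_p(x, y, tail)
    out$df <- out$n - 2L
    return(out)
  }
  z <- as.matrix(covariates)
  if (!is.null(names(x)) && !is.null(names(y)) && !is.null(rownames(z))) {
    common <- Reduce(intersect, list(names(x), names(y), rownames(z)))
    x <- x[common]; y <- y[common]; z <- z[common, , drop = FALSE]
  }
  use <- !is.na(x) & !is.na(y) & !apply(z, 1L, anyNA)
  n <- sum(use)
  xx <- x[use]; yy <- y[use]; zz <- z[use, , drop = FALSE]
  mm <- cbind(1, zz)
  qrm <- qr(mm)
  k <- qrm$rank - 1L                       # independent covariates
  if (qrm$rank < ncol(mm))
    message("dropped ", ncol(mm) - qrm$rank, " collinear covariate(s)")
  if (n <= k + 2L)
    return(list(r = NA_real_, n = n, df = n - 2L - k, p_value = NA_real_))
  rx <- qr.resid(qrm, xx)
  ry <- qr.resid(qrm, yy)
  # a series fully explained by the covariates has no residual signal:
  # its partial correlation is 0 (guard against correlating fp noise)
  degen <- function(res, orig) {
    v0 <- stats::var(orig)
    v0 == 0 || stats::var(res) <= 1e-12 * v0
  }
  df <- n - 2L - k
  if (degen(rx, xx) || degen(ry, yy))
    return(list(r = 0, n = n, df = df, p_value = 1))
  r <- stats::cor(rx, ry)
  list(r = r, n = n, df = df, p_value = cor_p_from_r(r, df, tail))
}

#' Select partial correlates passing statistical and literature filters
#'
#' For every probe other than the target, computes the partial correlation
#' with the target expression controlling for genotype at the given
#' markers (coded B = -1 / D = +1; strains with H or U calls at a control
#' marker are dropped).  Probes pass when the partial-correlation p is
#' below `p_max` and the literature correlation of their gene symbol
#' exceeds `lit_min` (both strict); missing literature entries fail the
#' literature filter and are counted.  Results are ranked by `|r|`
#' descending.
#'
#' @param expr An [expr_matrix()].
#' @param target_probe Probe id of the target gene.
#' @param geno A [geno_matrix()] covering the expression strains.
#' @param control_markers Marker ids to control for.
#' @param literature Data frame with columns `symbol` and `r` (precomputed
#'   literature correlations), or `NULL` for an empty table.
#' @param p_max,lit_min Filter thresholds (defaults 0.001 and 0.5).
#' @param tail p-value convention.
#' @return Data frame `probe`, `symbol`, `r`, `n`, `p_value`, `lit_r`,
#'   ranked by `|r|`; attribute `"n_missing_literature"` counts probes
#'   that failed for lack of a literature entry.
#' @export
select_partial_correlates <- function(expr, target_probe, geno,
                                      control_markers, literature,
                                      p_max = 0.001, lit_min = 0.5,
                                      tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(inherits(expr, "expr_matrix"))
  if (!target_probe %in% rownames(expr$values))
    stop("target probe not in expression matrix")
  if (!all(control_markers %in% geno$map$marker))
    stop("control marker(s) missing from the genotype map")
  x <- code_genotypes(geno)[, control_markers, drop = FALSE]
  common <- intersect(colnames(expr$values), rownames(x))
  z <- x[common, , drop = FALSE]
  target <- expr$values[target_probe, common]
  lit <- if (is.null(literature))
    data.frame(symbol = character(), r = numeric()) else literature

  others <- setdiff(rownames(expr$values), target_probe)
  res <- lapply(others, function(p) {
    pc <- partial_correlation(expr$values[p, common], target, z, tail)
    data.frame(probe = p,
               symbol = expr$annotation$symbol[
                 match(p, expr$annotation$probe)],
               r = pc$r, n = pc$n, p_value = pc$p_value)
  })
  res <- do.call(rbind, res)
  res$lit_r <- lit$r[match(res$symbol, lit$symbol)]
  missing_lit <- !is.na(res$p_value) & res$p_value < p_max &
    is.na(res$lit_r)
  keep <- !is.na(res$p_value) & res$p_value < p_max &
    !is.na(res$lit_r) & res$lit_r > lit_min
  out <- res[keep, , drop = FALSE]
  out <- out[order(-abs(out$r), out$probe), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_literature") <- sum(missing_lit)
  out
}

#' Thresholded coexpression network edges
#'
#' Undirected edges between member probes with `|r|` above
#' `edge_threshold` (strict), labelled `strong` (`|r| >= strong`), `weak`
#' (`|r| < weak`) or `mid`, with the sign retained.
#'
#' @param expr An [expr_matrix()].
#' @param members Probe ids (subset of the expression probes).
#' @param edge_threshold,strong,weak Correlation magnitude thresholds
#'   (defaults 0.3 / 0.7 / 0.5).
#' @return Data frame `a`, `b`, `r`, `n`, `class`, `sign`.
#' @export
build_network <- function(expr, members, edge_threshold = 0.3,
                          strong = 0.7, weak = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!all(members %in% rownames(expr$values)))
    stop("member probe(s) missing from expression matrix")
  m <- length(members)
  rows <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    pr <- pearson_with_p(expr$values[members[i], ],
                         expr$values[members[j], ])
    if (!is.na(pr$r) && abs(pr$r) > edge_threshold) {
      rows[[length(rows) + 1L]] <- data.frame(
        a = members[i], b = members[j], r = pr$r, n = pr$n,
        class = if (abs(pr$r) >= strong) "strong"
                else if (abs(pr$r) < weak) "weak" else "mid",
        sign = ifelse(pr$r >= 0, "+", "-"))
    }
  }
  if (!length(rows))
    return(data.frame(a = character(), b = character(), r = numeric(),
                      n = integer(), class = character(),
                      sign = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module eigengene: first principal component of a gene set
#'
#' PC1 of the standardized member submatrix with strains as observations
#' (correlation-matrix PCA, so probes with different dynamic range weigh
#' equally).  The variance explained is the leading eigenvalue over the
#' trace; the signature sign is oriented so that its mean correlation with
#' the members is positive.
#'
#' @param expr An [expr_matrix()].
#' @param members At least 2 probe ids.
#' @return List of class `module_signature`: `members`, `signature`
#'   (named per-strain score), `variance_explained`, `loadings`.
#' @export
module_pc1 <- function(expr, members) {
  stopifnot(inherits(expr, "expr_matrix"), length(members) >= 2L)
  if (!all(members %in% rownames(expr$values)))
    stop("member probe(s) missing from expression matrix")
  sub <- expr$values[members, , drop = FALSE]
  keep <- !apply(sub, 2L, anyNA)
  sub <- sub[, keep, drop = FALSE]
  if (ncol(sub) < 3L) stop("need >= 3 strains with complete member data")
  s <- scale(t(sub))                        # strains x members
  cc <- stats::cor(s)
  ei <- eigen(cc, symmetric = TRUE)
  v1 <- ei$vectors[, 1L]
  score <- as.vector(s %*% v1)
  names(score) <- rownames(s)
  if (mean(stats::cor(score, s)) < 0) { score <- -score; v1 <- -v1 }
  structure(list(members = members,
                 signature = score,
                 variance_explained = ei$values[1L] / sum(ei$values),
                 loadings = stats::setNames(v1, members)),
            class = "module_signature")
}

#' @export
print.module_signature <- function(x, ...) {
  cat(sprintf("module_signature: %d members, PC1 explains %.1f%% of covariation\n",
              length(x$members), 100 * x$variance_explained))
  invisible(x)
}

#' Top correlates of a reference profile
#'
#' Ranks all probes by `|r|` with the reference (a probe id or a named
#' per-strain series such as a module signature), ties broken by probe id.
#'
#' @param reference Probe id present in `expr`, or a named numeric vector.
#' @param expr An [expr_matrix()].
#' @param n Number of correlates to return (default 500).
#' @param tail p-value convention.
#' @return Data frame `probe`, `symbol`, `r`, `n`, `p_value` (top `n`
#'   rows).
#' @export
top_correlates <- function(reference, expr, n = 500,
                           tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(inherits(expr, "expr_matrix"))
  ref <- if (is.character(reference) && length(reference) == 1L) {
    if (!reference %in% rownames(expr$values))
      stop("reference probe not in expression matrix")
    expr$values[reference, ]
  } else reference
  if (sum(!is.na(ref)) < 3L) stop("reference defined on < 3 strains")
  res <- lapply(rownames(expr$values), function(p) {
    pr <- pearson_with_p(ref, expr$values[p, ], tail)
    data.frame(probe = p,
               symbol = expr$annotation$symbol[
                 match(p, expr$annotation$probe)],
               r = pr$r, n = pr$n, p_value = pr$p_value)
  })
  res <- do.call(rbind, res)
  res <- res[!is.na(res$r), , drop = FALSE]
  res <- res[order(-abs(res$r), res$probe), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, n)
}
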