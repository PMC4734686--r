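# Allele-specific expression calling from F1 replicate read counts.
#
# Pipeline per SNP: replicate allelic ratios -> IQR outlier filter ->
# merge concordant replicates -> chi-square goodness-of-fit against a
# balanced 1:1 expectation -> BH false discovery control within tissue ->
# gene-level imbalance calls.

#' Allelic ratio
#'
#' Reference-allele reads divided by total reads at a SNP.  In a B6xD2 F1
#' the reference is the B6 allele, so a ratio below 0.5 means higher
#' expression of the D2 copy.
#'
#' @param ref_count,alt_count Nonnegative read counts (vectorised).
#' @return `ref / (ref + alt)`; `NA` where the total is zero (such SNPs
#'   are dropped by the caller).
#' @export
allelic_ratio <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  ifelse(total > 0, ref_count / total, NA_real_)
}

#' Tukey IQR outlier mask
#'
#' Flags values strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` where the
#' quartiles are computed by linear interpolation between order statistics
#' (the standard type-7 estimator); the quantile type is configurable
#' since the fences move slightly with the estimator.
#'
#' @param ratios Numeric vector (at least 1 value).
#' @param quartile_type Quantile type passed to [stats::quantile()].
#' @return Logical mask, `TRUE` = outlier.
#' @export
iqr_outlier_mask <- function(ratios, quartile_type = 7) {
  if (!length(ratios)) stop("need at least one ratio")
  q <- stats::quantile(ratios, c(0.25, 0.75), na.rm = TRUE,
                       names = FALSE, type = quartile_type)
  iqr <- q[2L] - q[1L]
  !is.na(ratios) & (ratios < q[1L] - 1.5 * iqr | ratios > q[2L] + 1.5 * iqr)
}

#' Merge counts over concordant (non-outlier) replicates
#'
#' @param ref_counts,alt_counts Per-replicate counts.
#' @param mask Logical outlier mask from [iqr_outlier_mask()].
#' @return List with `ref` and `alt`, the component-wise sums over
#'   replicates not flagged.
#' @export
merge_concordant <- function(ref_counts, alt_counts, mask) {
  stopifnot(length(ref_counts) == length(alt_counts),
            length(mask) == length(ref_counts))
  if (all(mask)) stop("all replicates flagged as outliers")
  list(ref = sum(ref_counts[!mask]), alt = sum(alt_counts[!mask]))
}

#' Chi-square goodness-of-fit test for allelic imbalance
#'
#' Tests merged counts against the balanced 1:1 expectation:
#' `chi2 = (ref - E)^2 / E + (alt - E)^2 / E` with `E = total / 2`, 1
#' degree of freedom, upper-tail p, no continuity correction (two-sided by
#' construction).
#'
#' @param merged_ref,merged_alt Merged counts (vectorised; total > 0).
#' @return Data frame with `chi2` and `p_value`.
#' @export
chi_square_imbalance <- function(merged_ref, merged_alt) {
  total <- merged_ref + merged_alt
  if (any(total <= 0)) stop("total count must be > 0")
  e <- total / 2
  chi2 <- (merged_ref - e)^2 / e + (merged_alt - e)^2 / e
  data.frame(chi2 = chi2,
             p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up q-values via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Allelic fold difference
#'
#' `max(r, 1 - r) / min(r, 1 - r)`: how many-fold the more-expressed
#' allele exceeds the other.
#'
#' @param ratio Allelic ratio(s) in `[0, 1]`.
#' @return Fold difference(s) `>= 1` (`Inf` for monoallelic ratios).
#' @export
fold_difference <- function(ratio) {
  pmax(ratio, 1 - ratio) / pmin(ratio, 1 - ratio)
}

#' Call allele-specific expression from replicate counts
#'
#' Runs the full caller on an [allele_counts()] table.  Replicates with
#' zero coverage at a SNP are ignored; outlier replicates are removed by
#' the IQR rule on allelic ratios; merged SNPs below `min_depth` total
#' reads are dropped (degenerate chi-square guard).  q-values are computed
#' within each tissue by default (`fdr_scope = "global"` pools all SNPs).
#' A gene is called imbalanced in a tissue when at least one of its SNPs
#' has `q < fdr_threshold` and allelic fold difference `> fold_threshold`
#' (both strict).
#'
#' @param counts An [allele_counts()] table (or data frame with the same
#'   columns).
#' @param fdr_threshold FDR threshold (default 0.1).
#' @param fold_threshold Fold-difference threshold (default 1.25).
#' @param min_depth Minimum merged total reads per SNP (default 10).
#' @param quartile_type Quartile estimator for the IQR rule.
#' @param fdr_scope `"tissue"` (default) or `"global"` FDR family.
#' @return List of class `ase_calls`: `snp` (per-SNP merged counts, ratio,
#'   chi2, p, q, fold, kept replicates), `gene` (per gene x tissue call
#'   with supporting SNPs), `dropped` (SNPs removed, with reasons).
#' @export
ase_call <- function(counts, fdr_threshold = 0.1, fold_threshold = 1.25,
                     min_depth = 10, quartile_type = 7,
                     fdr_scope = c("tissue", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!inherits(counts, "allele_counts")) counts <- allele_counts(counts)
  key <- paste(counts$gene, counts$chrom, counts$pos, counts$tissue,
               sep = "\r")
  idx <- split(seq_len(nrow(counts)), key)

  snp_rows <- vector("list", length(idx))
  drop_rows <- list()
  for (k in seq_along(idx)) {
    rows <- counts[idx[[k]], , drop = FALSE]
    head1 <- rows[1L, c("gene", "chrom", "pos", "ref_base", "alt_base",
                        "tissue")]
    tot <- rows$ref_count + rows$alt_count
    usable <- tot > 0
    if (!any(usable)) {
      drop_rows[[length(drop_rows) + 1L]] <-
        cbind(head1, reason = "no_reads")
      next
    }
    ratios <- rows$ref_count[usable] / tot[usable]
    mask <- iqr_outlier_mask(ratios, quartile_type)
    merged <- merge_concordant(rows$ref_count[usable],
                               rows$alt_count[usable], mask)
    total <- merged$ref + merged$alt
    if (total < min_depth) {
      drop_rows[[length(drop_rows) + 1L]] <-
        cbind(head1, reason = "low_depth")
      next
    }
    test <- chi_square_imbalance(merged$ref, merged$alt)
    snp_rows[[k]] <- cbind(
      head1,
      data.frame(
        n_replicates = sum(usable), n_outliers = sum(mask),
        kept_replicates = paste(rows$replicate_id[usable][!mask],
                                collapse = ","),
        merged_ref = merged$ref, merged_alt = merged$alt, total = total,
        allelic_ratio = merged$ref / total, chi2 = test$chi2,
        p_value = test$p_value))
  }
  snp <- do.call(rbind, snp_rows)
  if (is.null(snp) || !nrow(snp)) stop("no SNPs survived filtering")
  rownames(snp) <- NULL
  snp$q_value <- NA_real_
  if (fdr_scope == "tissue") {
    for (tis in unique(snp$tissue)) {
      sel <- snp$tissue == tis
      snp$q_value[sel] <- bh_fdr(snp$p_value[sel])
    }
  } else {
    snp$q_value <- bh_fdr(snp$p_value)
  }
  # fold from integer counts: algebraically equal to
  # fold_difference(ratio) but exact at threshold boundaries like 1.25
  snp$fold <- pmax(snp$merged_ref, snp$merged_alt) /
    pmin(snp$merged_ref, snp$merged_alt)
  snp$pass <- snp$q_value < fdr_threshold & snp$fold > fold_threshold

  gkey <- paste(snp$gene, snp$tissue, sep = "\r")
  gene <- do.call(rbind, lapply(split(seq_len(nrow(snp)), gkey),
                                function(ii) {
    s <- snp[ii, , drop = FALSE]
    sup <- s$pass
    data.frame(gene = s$gene[1L], tissue = s$tissue[1L],
               imbalanced = any(sup), n_snps = nrow(s),
               supporting_snps = paste(s$pos[sup], collapse = ","),
               fold_difference = if (any(sup)) max(s$fold[sup])
                                 else max(s$fold),
               min_q = min(s$q_value))
  }))
  rownames(gene) <- NULL
  dropped <- if (length(drop_rows)) do.call(rbind, drop_rows) else NULL
  structure(list(snp = snp, gene = gene, dropped = dropped,
                 params = list(fdr_threshold = fdr_threshold,
                               fold_threshold = fold_threshold,
                               min_depth = min_depth,
                               quartile_type = quartile_type,
                               fdr_scope = fdr_scope)),
            class = "ase_calls")
}

#' @export
print.ase_calls <- function(x, ...) {
  cat(sprintf("ase_calls: %d SNPs, %d gene x tissue calls (%d imbalanced), %d dropped\n",
              nrow(x$snp), nrow(x$gene), sum(x$gene$imbalanced),
              if (is.null(x$dropped)) 0L else nrow(x$dropped)))
  invisible(x)
}
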