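# Rule-based screens for transcripts and phenotypes downstream of a
# target gene's local variation.

#' Selection criteria for downstream screens
#'
#' @param gene Target gene symbol.
#' @param chrom,mb Target gene location (chromosome, megabases).
#' @param trans_window_mb Width of the trans-eQTL window overlapping the
#'   target locus (default 4 Mb).
#' @param window_style `"centered"` (default; `mb +/- width/2`) or
#'   `"flank"` (`mb +/- width`).
#' @param min_expression Minimum mean log2 expression (default 8, strict
#'   `>`).
#' @param min_lod Minimum peak LOD (default 2, strict `>`; a suggestive
#'   trans-eQTL).
#' @param cor_p_max Significance cut-off for the correlation with the
#'   target (default 0.01, strict `<`).
#' @param phenotype_window_mb Window around the target locus for phenotype
#'   QTL peaks (default 2 Mb, applied on each side).
#' @param phenotype_cor_p_max Correlation cut-off for phenotypes (default
#'   0.005, strict `<`).
#' @param phenotype_min_lod Minimum phenotype peak LOD (default 2, strict
#'   `>`).
#' @return A validated list of class `target_criteria`.
#' @export
target_criteria <- function(gene, chrom, mb, trans_window_mb = 4,
                            window_style = c("centered", "flank"),
                            min_expression = 8, min_lod = 2,
                            cor_p_max = 0.01, phenotype_window_mb = 2,
                            phenotype_cor_p_max = 0.005,
                            phenotype_min_lod = 2) {
  window_style <- match.arg(window_style)
  stopifnot(trans_window_mb > 0, phenotype_window_mb > 0,
            cor_p_max > 0, cor_p_max <= 1,
            phenotype_cor_p_max > 0, phenotype_cor_p_max <= 1)
  structure(as.list(environment()), class = "target_criteria")
}

target_window <- function(criteria) {
  half <- if (criteria$window_style == "centered")
    criteria$trans_window_mb / 2 else criteria$trans_window_mb
  c(criteria$mb - half, criteria$mb + half)
}

#' Transcripts putatively downstream of a target locus
#'
#' Selects probes that (i) have mean expression above
#' `criteria$min_expression`, (ii) carry a peak with LOD above
#' `criteria$min_lod` whose marker lies inside the window overlapping the
#' target locus on the target chromosome (boundaries inclusive), and
#' (iii) are not the target gene itself; each hit is annotated with its
#' Pearson correlation against the target expression and a significance
#' flag at `criteria$cor_p_max`.  The filters commute, so the result does
#' not depend on their order.
#'
#' @param expr An [expr_matrix()].
#' @param peaks Data frame of per-probe peaks (`probe`, `peak_chr`,
#'   `peak_mb`, `peak_lod`), e.g. from [map_eqtl()].
#' @param criteria A [target_criteria()].
#' @param target_values Optional named per-strain vector of target
#'   expression; required when no probe of `expr` is annotated with the
#'   target symbol.
#' @param tail p-value convention for the correlations.
#' @return Data frame of hits with `probe`, `symbol`, `mean_expr`, peak
#'   location and LOD, `r`, `n`, `p_value`, `significant_cor`.
#' @export
find_downstream_transcripts <- function(expr, peaks, criteria,
                                        target_values = NULL,
                                        tail = c("one.sided",
                                                 "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(criteria, "target_criteria"))
  target_probes <- expr$annotation$probe[
    expr$annotation$symbol == criteria$gene]
  if (is.null(target_values)) {
    if (!length(target_probes))
      stop("target gene not in expression matrix; supply 'target_values'")
    target_values <- expr$values[target_probes[1L], ]
  }
  win <- target_window(criteria)
  mean_expr <- rowMeans(expr$values, na.rm = TRUE)
  pk <- peaks[match(rownames(expr$values), peaks$probe), , drop = FALSE]

  pass <- !is.na(pk$peak_lod) &
    mean_expr > criteria$min_expression &
    pk$peak_lod > criteria$min_lod &
    as.character(pk$peak_chr) == as.character(criteria$chrom) &
    pk$peak_mb >= win[1L] & pk$peak_mb <= win[2L] &
    !(rownames(expr$values) %in% target_probes)
  hits <- which(pass)
  if (!length(hits))
    return(data.frame(probe = character(), symbol = character(),
                      mean_expr = numeric(), peak_chr = character(),
                      peak_mb = numeric(), peak_lod = numeric(),
                      r = numeric(), n = integer(), p_value = numeric(),
                      significant_cor = logical()))
  out <- do.call(rbind, lapply(hits, function(i) {
    pr <- pearson_with_p(expr$values[i, ], target_values, tail)
    data.frame(probe = rownames(expr$values)[i],
               symbol = expr$annotation$symbol[i],
               mean_expr = mean_expr[i],
               peak_chr = pk$peak_chr[i], peak_mb = pk$peak_mb[i],
               peak_lod = pk$peak_lod[i],
               r = pr$r, n = pr$n, p_value = pr$p_value,
               significant_cor = !is.na(pr$p_value) &
                 pr$p_value < criteria$cor_p_max)
  }))
  out <- out[order(-out$peak_lod, out$probe), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenotypes mapped to or correlated with a target locus
#'
#' Two screens over a phenotype table: `mapped` contains traits whose
#' genome-scan peak exceeds `criteria$phenotype_min_lod` and lies within
#' `criteria$phenotype_window_mb` of the target locus (inclusive, on the
#' target chromosome); `correlated` contains traits whose correlation with
#' the target expression has `p < criteria$phenotype_cor_p_max`, reported
#' with `(record_id, r, n)`.  Traits with fewer than `min_overlap` strains
#' in common with the target are skipped and counted.
#'
#' @param pheno A [pheno_table()].
#' @param geno A [geno_matrix()] for the mapping screen.
#' @param target_values Named per-strain vector of target gene expression.
#' @param criteria A [target_criteria()].
#' @param min_overlap Minimum shared strains for a correlation (default
#'   6).
#' @param tail p-value convention.
#' @return List with data frames `mapped` and `correlated`, and
#'   `n_skipped`.
#' @export
screen_phenotypes <- function(pheno, geno, target_values, criteria,
                              min_overlap = 6,
                              tail = c("one.sided", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(inherits(pheno, "pheno_table"),
            inherits(criteria, "target_criteria"))
  mapped <- list(); correlated <- list(); skipped <- 0L
  for (i in seq_len(nrow(pheno$values))) {
    y <- pheno$values[i, ]
    rid <- pheno$info$record_id[i]
    if (sum(!is.na(y)) >= 3L) {
      sc <- marker_regression(y, geno)
      if (!all(is.na(sc$lod))) {
        pk <- find_peak(sc)
        if (pk$lod > criteria$phenotype_min_lod &&
            as.character(pk$chr) == as.character(criteria$chrom) &&
            abs(pk$mb - criteria$mb) <= criteria$phenotype_window_mb) {
          mapped[[length(mapped) + 1L]] <-
            data.frame(record_id = rid, peak_marker = pk$marker,
                       peak_chr = pk$chr, peak_mb = pk$mb,
                       peak_lod = pk$lod)
        }
      }
    }
    common <- intersect(names(y)[!is.na(y)],
                        names(target_values)[!is.na(target_values)])
    if (length(common) < min_overlap) { skipped <- skipped + 1L; next }
    pr <- pearson_with_p(y[common], target_values[common], tail)
    if (!is.na(pr$p_value) && pr$p_value < criteria$phenotype_cor_p_max) {
      correlated[[length(correlated) + 1L]] <-
        data.frame(record_id = rid, r = pr$r, n = pr$n,
                   p_value = pr$p_value)
    }
  }
  empty_map <- data.frame(record_id = character(),
                          peak_marker = character(),
                          peak_chr = character(), peak_mb = numeric(),
                          peak_lod = numeric())
  empty_cor <- data.frame(record_id = character(), r = numeric(),
                          n = integer(), p_value = numeric())
  list(mapped = if (length(mapped)) do.call(rbind, mapped) else empty_map,
       correlated = if (length(correlated)) do.call(rbind, correlated)
                    else empty_cor,
       n_skipped = skipped)
}
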