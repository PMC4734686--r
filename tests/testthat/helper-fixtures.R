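# Small in-code fixtures shared across test files.

# hand-written two-strain, three-marker genotype file
write_geno_fixture <- function(path = tempfile(fileext = ".geno"),
                               cell22 = "B") {
  writeLines(c(
    "@type:riset",
    "@mat:B",
    "# tiny fixture",
    paste("Chr", "Locus", "cM", "Mb", "S1", "S2", sep = "\t"),
    paste("1", "m1", "0", "3", "B", "D", sep = "\t"),
    paste("1", "m2", "1", "5", "B", cell22, sep = "\t"),
    paste("2", "m3", "0", "2", "D", "D", sep = "\t")), path)
  path
}

ok_names <- function(nm) {
  !is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm)
}

# wrap a probes x strains matrix into an expr_matrix with default annotation
make_expr <- function(values, chr = "1", mb = NULL, symbol = NULL) {
  if (!ok_names(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (!ok_names(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  n <- nrow(values)
  expr_matrix(values, data.frame(
    probe = rownames(values),
    symbol = if (is.null(symbol)) toupper(rownames(values)) else symbol,
    chr = rep_len(chr, n),
    mb = if (is.null(mb)) seq_len(n) * 10 else rep_len(mb, n)))
}

# genotype object with given coded matrix (+1 = D, -1 = B), one chromosome
make_geno <- function(coded, chr = NULL, mb = NULL) {
  calls <- ifelse(coded > 0, "D", "B")
  if (!ok_names(rownames(calls)))
    rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  if (!ok_names(colnames(calls)))
    colnames(calls) <- sprintf("m%02d", seq_len(ncol(calls)))
  geno_matrix(calls, data.frame(
    marker = colnames(calls),
    chr = if (is.null(chr)) rep("1", ncol(calls)) else chr,
    mb = if (is.null(mb)) seq_len(ncol(calls)) * 5 else mb))
}

# a bare scan data frame for interval tests
make_scan <- function(lod, mb = NULL, chr = "1") {
  n <- length(lod)
  out <- data.frame(marker = sprintf("m%02d", seq_len(n)),
                    chr = rep_len(chr, n),
                    mb = if (is.null(mb)) seq_len(n) * 10 else mb,
                    n = 20L, lrs = lod * 2 * log(10), lod = lod,
                    additive = 0, capped = FALSE)
  class(out) <- c("qtl_scan", "data.frame")
  out
}
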