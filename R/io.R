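# Domain containers and tabular readers/writers.
#
# All tabular formats are UTF-8, tab-delimited, with '#'-prefixed comment
# lines allowed.  Marker and gene positions are megabase floats; SNP
# positions in allele-count tables are 1-based base-pair integers.

GENO_CODES <- c("B", "D", "H", "U")

#' Genotype matrix for a biparental RI panel
#'
#' Bundles a strains-by-markers call matrix with its marker map.  Calls use
#' the GeneNetwork convention: `B` and `D` for the two parental homozygotes,
#' `H` for a (usually erroneous) heterozygous call, `U` for unknown.
#'
#' @param calls Character matrix, strains in rows (rownames), markers in
#'   columns (colnames), entries in `B/D/H/U`.
#' @param map Data frame with columns `marker`, `chr`, `mb` and optionally
#'   `cm`, one row per column of `calls`, in the same order.
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   and `map`.
#' @examples
#' calls <- rbind(S1 = c("B", "B", "D"), S2 = c("D", "B", "B"))
#' colnames(calls) <- c("m1", "m2", "m3")
#' map <- data.frame(marker = colnames(calls), chr = "1", mb = c(10, 20, 30))
#' g <- geno_matrix(calls, map)
#' @export
geno_matrix <- function(calls, map) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix")
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls)))
    stop("strain ids (rownames of 'calls') must be present and unique")
  if (is.null(colnames(calls)))
    stop("marker ids (colnames of 'calls') must be present")
  bad <- setdiff(unique(as.vector(calls)), GENO_CODES)
  if (length(bad))
    stop("invalid genotype codes: ", paste(bad, collapse = ", "))
  map <- validate_marker_map(map)
  if (!identical(as.character(map$marker), colnames(calls)))
    stop("marker map does not match the columns of 'calls'")
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

validate_marker_map <- function(map) {
  need <- c("marker", "chr", "mb")
  if (!all(need %in% names(map)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker))
    stop("duplicated marker id in map: ",
         map$marker[duplicated(map$marker)][1L])
  map$marker <- as.character(map$marker)
  map$chr <- as.character(map$chr)
  map$mb <- as.numeric(map$mb)
  if (any(!is.na(map$mb) & map$mb < 0)) stop("marker Mb positions must be >= 0")
  if (!"cm" %in% names(map)) map$cm <- NA_real_
  map[, c("marker", "chr", "mb", "cm")]
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chr))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Strain identifiers of a container
#' @param x A `geno_matrix`, `expr_matrix` or `pheno_table`.
#' @return Character vector of strain ids.
#' @export
strains <- function(x) {
  if (inherits(x, "geno_matrix")) rownames(x$calls)
  else if (inherits(x, "expr_matrix")) colnames(x$values)
  else if (inherits(x, "pheno_table")) colnames(x$values)
  else stop("no strains() method for this object")
}

#' Numerically code RI genotype calls
#'
#' Maps `B` to -1 and `D` to +1 so that a positive additive effect means
#' higher trait values with the D (paternal, in BXD) allele.  `U` is always
#' `NA`; `H` is `NA` (strain dropped at that marker) or 0 depending on
#' `het`.
#'
#' @param geno A [geno_matrix()].
#' @param het `"drop"` (default) to exclude heterozygous calls, `"zero"`
#'   to code them 0.
#' @return Numeric strains-by-markers matrix.
#' @export
code_genotypes <- function(geno, het = c("drop", "zero")) {
  het <- match.arg(het)
  key <- c(B = -1, D = 1, H = if (het == "zero") 0 else NA_real_,
           U = NA_real_)
  x <- key[geno$calls]
  matrix(x, nrow(geno$calls), ncol(geno$calls),
         dimnames = dimnames(geno$calls))
}

# --- .geno dialect -------------------------------------------------------

#' Read a GeneNetwork-style .geno file
#'
#' The dialect: optional `@`-prefixed metadata lines, optional `#` comment
#' lines, a header row `Chr<TAB>Locus<TAB>cM<TAB>Mb<TAB><strain1>...`, then
#' one row per marker with `B/D/H/U` calls.  Unknown call symbols are
#' mapped to `U` with a single warning reporting the count.
#'
#' @param path Path to the file.
#' @return A [geno_matrix()]; `@` metadata lines are kept in attribute
#'   `"metadata"`.
#' @export
read_geno <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "@")]
  keep <- !startsWith(lines, "@") & !startsWith(lines, "#") &
    nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (!length(body)) stop("no header row found in ", path)
  hdr <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 5L || !identical(hdr[1:4], c("Chr", "Locus", "cM", "Mb")))
    stop("header must start with Chr, Locus, cM, Mb followed by strain ids")
  strain_ids <- hdr[-(1:4)]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  arity <- lengths(rows)
  if (any(arity != length(hdr))) {
    i <- which(arity != length(hdr))[1L]
    stop(sprintf("line %d has %d fields, expected %d",
                 lineno[-1L][i], arity[i], length(hdr)))
  }
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab[, 2L]))
    stop("duplicated marker id: ", tab[duplicated(tab[, 2L]), 2L][1L])
  calls <- t(tab[, -(1:4), drop = FALSE])
  unknown <- !(calls %in% GENO_CODES)
  if (any(unknown)) {
    warning(sum(unknown), " unknown genotype call(s) set to U")
    calls[unknown] <- "U"
  }
  dimnames(calls) <- list(strain_ids, tab[, 2L])
  map <- data.frame(marker = tab[, 2L], chr = tab[, 1L],
                    mb = as.numeric(tab[, 4L]), cm = as.numeric(tab[, 3L]))
  out <- geno_matrix(calls, map)
  attr(out, "metadata") <- meta
  out
}

#' Write a genotype matrix in the .geno dialect
#'
#' Output is canonical: `write_geno(read_geno(f))` is byte-identical to the
#' canonicalized form of `f` (a second read/write round trip is a fixed
#' point).
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  meta <- attr(geno, "metadata")
  hdr <- paste(c("Chr", "Locus", "cM", "Mb", rownames(geno$calls)),
               collapse = "\t")
  num <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE,
                                                   scientific = FALSE))
  body <- vapply(seq_len(ncol(geno$calls)), function(j) {
    paste(c(geno$map$chr[j], geno$map$marker[j], num(geno$map$cm[j]),
            num(geno$map$mb[j]), geno$calls[, j]), collapse = "\t")
  }, character(1L))
  writeLines(c(meta, hdr, body), path, useBytes = TRUE)
  invisible(path)
}

# --- expression ----------------------------------------------------------

#' Expression matrix with gene annotation
#'
#' @param values Numeric probes-by-strains matrix of (typically log2)
#'   expression, usually strain means.
#' @param annotation Data frame with columns `probe`, `symbol`, `chr`, `mb`
#'   (gene location), one row per row of `values`.
#' @param replicates Optional replicate-level data: a list with elements
#'   `values` (probes-by-samples numeric matrix) and `strain` (character
#'   vector assigning each sample column to a strain).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, annotation, replicates = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) rownames(values) <- annotation$probe
  need <- c("probe", "symbol", "chr", "mb")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$probe)) stop("duplicated probe ids")
  if (!identical(as.character(annotation$probe), rownames(values)))
    stop("annotation does not match the rows of 'values'")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("strain ids (colnames of 'values') must be present and unique")
  if (!is.null(replicates)) {
    stopifnot(is.list(replicates),
              all(c("values", "strain") %in% names(replicates)),
              ncol(replicates$values) == length(replicates$strain))
    if (!all(replicates$strain %in% colnames(values)))
      stop("replicate strains not among strain columns")
  }
  structure(list(values = values,
                 annotation = annotation[, need],
                 replicates = replicates),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d strains%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$replicates)) "" else
                sprintf(" (+%d replicate samples)",
                        ncol(x$replicates$values))))
  invisible(x)
}

#' Read an expression TSV
#'
#' Expected columns: `probe`, `symbol`, `chr`, `mb`, then one column per
#' strain.  Replicate-level files use `strain:replicate` column names
#' (e.g. `BXD1:1`, `BXD1:2`); strain means are then computed on read.
#' Empty cells or `NA` are recorded as missing, never as zero.
#'
#' @param path Path to the file.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  need <- c("probe", "symbol", "chr", "mb")
  if (!all(need %in% names(tab)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  samp_cols <- setdiff(names(tab), need)
  vals <- matrix(NA_real_, nrow(tab), length(samp_cols),
                 dimnames = list(tab$probe, samp_cols))
  for (j in seq_along(samp_cols)) {
    raw <- trimws(tab[[samp_cols[j]]])
    miss <- is.na(raw) | !nzchar(raw) | raw == "NA"
    v <- suppressWarnings(as.numeric(raw))
    v[miss] <- NA_real_
    bad <- !miss & is.na(v)
    if (any(bad))
      stop(sprintf("non-numeric expression value '%s' for probe %s, column %s",
                   raw[bad][1L], tab$probe[bad][1L], samp_cols[j]))
    vals[, j] <- v
  }
  ann <- data.frame(probe = tab$probe, symbol = tab$symbol,
                    chr = as.character(tab$chr), mb = as.numeric(tab$mb))
  if (any(grepl(":", samp_cols, fixed = TRUE))) {
    strain_of <- sub(":.*$", "", samp_cols)
    ustr <- unique(strain_of)
    means <- vapply(ustr, function(s)
      rowMeans(vals[, strain_of == s, drop = FALSE], na.rm = TRUE),
      numeric(nrow(vals)))
    means <- matrix(means, nrow(vals), length(ustr),
                    dimnames = list(rownames(vals), ustr))
    means[is.nan(means)] <- NA_real_
    expr_matrix(means, ann,
                replicates = list(values = vals, strain = strain_of))
  } else {
    expr_matrix(vals, ann)
  }
}

#' Write an expression TSV
#'
#' Writes replicate-level values when present (with `strain:replicate`
#' columns), otherwise strain means.  `read_expression()` inverts it.
#'
#' @param expr An [expr_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!is.null(expr$replicates)) {
    vals <- expr$replicates$values
  } else {
    vals <- expr$values
  }
  num <- function(x) ifelse(is.na(x), "NA",
                            format(x, trim = TRUE, scientific = FALSE,
                                   digits = 15))
  hdr <- paste(c("probe", "symbol", "chr", "mb", colnames(vals)),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(expr$annotation$probe[i], expr$annotation$symbol[i],
            expr$annotation$chr[i], num(expr$annotation$mb[i]),
            num(vals[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

# --- allele counts -------------------------------------------------------

ALLELE_COUNT_COLS <- c("gene", "chrom", "pos", "ref_base", "alt_base",
                       "replicate_id", "ref_count", "alt_count", "tissue")

#' Validate an allele-count table
#'
#' Per-SNP, per-replicate parental read counts from F1 hybrids: the input
#' of the allele-specific expression caller.  `ref_count` counts reads
#' assigned to the reference (B6) allele, `alt_count` the alternative (D2)
#' allele.
#'
#' @param df Data frame with columns `gene`, `chrom`, `pos` (1-based bp),
#'   `ref_base`, `alt_base`, `replicate_id`, `ref_count`, `alt_count`,
#'   `tissue`.
#' @return The validated data frame with class `allele_counts` prepended.
#' @export
allele_counts <- function(df) {
  if (!all(ALLELE_COUNT_COLS %in% names(df)))
    stop("allele-count table needs columns: ",
         paste(ALLELE_COUNT_COLS, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$ref_count <- as.integer(df$ref_count)
  df$alt_count <- as.integer(df$alt_count)
  if (any(is.na(df$ref_count)) || any(is.na(df$alt_count)))
    stop("counts must be integers")
  if (any(df$ref_count < 0) || any(df$alt_count < 0))
    stop("negative read count")
  key <- paste(df$gene, df$chrom, df$pos, df$replicate_id, df$tissue,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (gene, chrom, pos, replicate, tissue) record")
  class(df) <- unique(c("allele_counts", class(df)))
  df
}

#' Read an allele-count TSV
#' @param path Path to the file.
#' @return An [allele_counts()] table.
#' @export
read_allele_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  allele_counts(df)
}

#' Write an allele-count TSV
#' @param counts An [allele_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts)[, ALLELE_COUNT_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- phenotypes ----------------------------------------------------------

#' Phenotype table
#'
#' @param values Numeric traits-by-strains matrix (missing allowed).
#' @param info Data frame with columns `record_id` and `description`, one
#'   row per row of `values`.
#' @return An object of class `pheno_table`.
#' @export
pheno_table <- function(values, info) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyDuplicated(info$record_id)) stop("duplicated record_id")
  if (!"description" %in% names(info)) info$description <- ""
  if (is.null(rownames(values))) rownames(values) <- info$record_id
  if (!identical(as.character(info$record_id), rownames(values)))
    stop("info does not match the rows of 'values'")
  structure(list(values = values,
                 info = info[, c("record_id", "description")]),
            class = "pheno_table")
}

#' Read a phenotype TSV (`record_id`, `description`, strain columns)
#' @param path Path to the file.
#' @return A [pheno_table()].
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  need <- c("record_id", "description")
  if (!all(need %in% names(tab)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  scols <- setdiff(names(tab), need)
  vals <- sapply(scols, function(s) {
    raw <- trimws(tab[[s]])
    miss <- is.na(raw) | !nzchar(raw) | raw == "NA"
    v <- suppressWarnings(as.numeric(raw))
    v[miss] <- NA_real_
    bad <- !miss & is.na(v)
    if (any(bad))
      stop(sprintf("non-numeric phenotype value '%s' for record %s, strain %s",
                   raw[bad][1L], tab$record_id[bad][1L], s))
    v
  })
  vals <- matrix(vals, nrow(tab), length(scols),
                 dimnames = list(tab$record_id, scols))
  pheno_table(vals, data.frame(record_id = tab$record_id,
                               description = tab$description))
}

#' Write a phenotype TSV
#' @param pheno A [pheno_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  num <- function(x) ifelse(is.na(x), "NA",
                            format(x, trim = TRUE, scientific = FALSE,
                                   digits = 15))
  hdr <- paste(c("record_id", "description", colnames(pheno$values)),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(pheno$values)), function(i) {
    paste(c(pheno$info$record_id[i], pheno$info$description[i],
            num(pheno$values[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Write a JSON run manifest (parameters, seed, package version)
#'
#' @param path Output path.
#' @param params Named list of parameters to record.
#' @param seed Integer seed used for the run, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params = list(), seed = NULL) {
  esc <- function(s) gsub('"', '\\\\"', s)
  fmt <- function(v) {
    if (is.null(v)) "null"
    else if (is.numeric(v) && length(v) == 1L) format(v, digits = 15)
    else paste0('"', esc(paste(as.character(v), collapse = ",")), '"')
  }
  fields <- c(
    sprintf('"package": "riqtl %s"',
            as.character(utils::packageVersion("riqtl"))),
    sprintf('"seed": %s', fmt(seed)),
    if (length(params))
      sprintf('"%s": %s', esc(names(params)), vapply(params, fmt, ""))
  )
  writeLines(paste0("{\n  ", paste(fields, collapse = ",\n  "), "\n}"),
             path)
  invisible(path)
}
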