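# Synthetic-data generators with known ground truth.
#
# The generators emulate the statistical structure of a biparental RI
# expression-genetics study: homozygous B/D genotypes with Markov linkage
# along each chromosome, expression built from additive genetic effects
# plus strain and replicate noise, overdispersed allele-specific read
# counts from F1 replicates, and strain-level phenotypes.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the simulated study conditions used throughout the
#' package's tests: 60 RI strains genotyped at 5 chromosomes x 20 markers
#' (2.5 Mb spacing, adjacent-marker recombination probability 0.05),
#' expression with strain-level variance 0.4 and replicate-level residual
#' variance 0.008 (log2 units squared) over 4 replicates, and
#' allele-specific counts from 6 F1 replicates with negative-binomial read
#' depths (mean 200, dispersion 10).
#'
#' @param n_strains Number of RI strains.
#' @param n_chrom,markers_per_chrom,spacing_mb Marker map specification.
#' @param recomb Probability that adjacent markers differ within a strain
#'   (Markov chain), in `[0, 0.5]`.
#' @param n_probes Number of expression probes.
#' @param effects `NULL` or a data frame `(probe, marker, effect)` of
#'   planted additive eQTL effects in log2 units (genotype coded B = -1,
#'   D = +1, so a positive effect raises expression with the D allele).
#' @param mu Baseline log2 expression.
#' @param var_strain Strain-level (non-additive-marker) variance.
#' @param var_resid Replicate-level residual variance (> 0).
#' @param replicates Replicates per strain for expression.
#' @param n_ase_genes,snps_per_gene,ase_replicates ASE table dimensions.
#' @param theta True reference-allele ratio(s) in `(0, 1)`, recycled over
#'   genes.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   per SNP and replicate (`size = depth_dispersion`).
#' @param outlier_rate Probability that a replicate of a SNP is an outlier.
#' @param outlier_shift Added to `theta` for outlier replicates (clamped
#'   to `[0.01, 0.99]`).
#' @param tissue Tissue label for simulated counts.
#' @param n_traits Number of phenotype traits.
#' @param trait_effects `NULL` or a data frame `(trait, marker, effect)`.
#' @param trait_var Residual variance of traits.
#' @param seed Integer seed; each generator draws from a stream derived
#'   from it (offsets 0-3) so a full simulated study is reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 60,
                       n_chrom = 5, markers_per_chrom = 20, spacing_mb = 2.5,
                       recomb = 0.05,
                       n_probes = 200, effects = NULL, mu = 8,
                       var_strain = 0.4, var_resid = 0.008, replicates = 4,
                       n_ase_genes = 50, snps_per_gene = 1,
                       ase_replicates = 6, theta = 0.5,
                       depth_mean = 200, depth_dispersion = 10,
                       outlier_rate = 0, outlier_shift = 0.4,
                       tissue = "sim",
                       n_traits = 10, trait_effects = NULL, trait_var = 1,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (recomb < 0 || recomb > 0.5) stop("'recomb' must be in [0, 0.5]")
  if (any(theta <= 0) || any(theta >= 1)) stop("'theta' must be in (0, 1)")
  if (var_strain < 0 || trait_var < 0) stop("variances must be >= 0")
  if (var_resid <= 0) stop("'var_resid' must be > 0")
  if (n_strains < 2) stop("need at least 2 strains")
  if (!is.null(effects) &&
      !all(c("probe", "marker", "effect") %in% names(effects)))
    stop("'effects' needs columns probe, marker, effect")
  if (!is.null(trait_effects) &&
      !all(c("trait", "marker", "effect") %in% names(trait_effects)))
    stop("'trait_effects' needs columns trait, marker, effect")
  class(cfg) <- "sim_config"
  cfg
}

sim_seed <- function(config, offset) {
  if (!is.null(config$seed)) set.seed(config$seed + offset)
  invisible(NULL)
}

#' Simulate RI genotypes with Markov linkage
#'
#' Per strain and chromosome the first marker is B or D with probability
#' 1/2 and each subsequent marker flips with probability `recomb`.  All
#' calls are homozygous (no H or U), as in a fully inbred panel.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()]; strains `SIM001...`, markers `c<chr>m<idx>`.
#' @export
simulate_ri_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim_seed(config, 0L)
  ns <- config$n_strains
  m <- config$markers_per_chrom
  blocks <- lapply(seq_len(config$n_chrom), function(chr) {
    g <- matrix(0L, ns, m)
    g[, 1L] <- stats::rbinom(ns, 1L, 0.5)
    if (m > 1L) {
      flips <- matrix(stats::rbinom(ns * (m - 1L), 1L, config$recomb),
                      ns, m - 1L)
      for (j in 2L:m) g[, j] <- (g[, j - 1L] + flips[, j - 1L]) %% 2L
    }
    g
  })
  g <- do.call(cbind, blocks)
  calls <- matrix(c("B", "D")[g + 1L], ns, ncol(g))
  rownames(calls) <- sprintf("SIM%03d", seq_len(ns))
  map <- data.frame(
    marker = as.vector(t(outer(seq_len(config$n_chrom), seq_len(m),
                               function(c, i) sprintf("c%dm%02d", c, i)))),
    chr = as.character(rep(seq_len(config$n_chrom), each = m)),
    mb = rep(seq_len(m) * config$spacing_mb, config$n_chrom))
  colnames(calls) <- map$marker
  geno_matrix(calls, map)
}

#' Simulate replicate-level expression with planted genetic effects
#'
#' Each replicate value is `mu + sum(effect * g) + strain deviate +
#' residual`, with `g` coded B = -1 / D = +1.  Probes are annotated at the
#' location of their planted marker (so planted eQTL are cis by
#' construction); probes without effects are spread round-robin across
#' markers.
#'
#' @param geno A [geno_matrix()] from [simulate_ri_genotypes()].
#' @param config A [sim_config()].
#' @return A list with `expr` (an [expr_matrix()] whose `values` are
#'   strain means over replicates) and `truth` (a list with per-probe
#'   analytic variance components and heritability, and the effect table).
#'   Analytic components assume equal allele frequencies (`Var(g) = 1`)
#'   and ignore linkage between planted markers.
#' @export
simulate_expression <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  sim_seed(config, 1L)
  g <- code_genotypes(geno)          # strains x markers, +-1
  ns <- nrow(g)
  np <- config$n_probes
  reps <- config$replicates
  probes <- sprintf("probe%03d", seq_len(np))

  genetic <- matrix(0, np, ns, dimnames = list(probes, rownames(g)))
  va_add <- numeric(np)
  eff <- config$effects
  if (!is.null(eff)) {
    eff$probe <- as.character(eff$probe)
    eff$marker <- as.character(eff$marker)
    if (!all(eff$probe %in% probes)) stop("unknown probe in 'effects'")
    if (!all(eff$marker %in% colnames(g))) stop("unknown marker in 'effects'")
    for (i in seq_len(nrow(eff))) {
      p <- eff$probe[i]
      genetic[p, ] <- genetic[p, ] + eff$effect[i] * g[, eff$marker[i]]
    }
    va_add <- vapply(probes, function(p)
      sum(eff$effect[eff$probe == p]^2), numeric(1L))
  }

  strain_dev <- matrix(stats::rnorm(np * ns, 0, sqrt(config$var_strain)),
                       np, ns)
  true_mean <- config$mu + genetic + strain_dev

  samples <- as.vector(t(outer(rownames(g), seq_len(reps), paste, sep = ":")))
  strain_of <- sub(":.*$", "", samples)
  repl <- true_mean[, strain_of, drop = FALSE] +
    matrix(stats::rnorm(np * ns * reps, 0, sqrt(config$var_resid)),
           np, ns * reps)
  colnames(repl) <- samples
  means <- t(apply(repl, 1L, function(v) tapply(v, strain_of, mean)))
  means <- means[, rownames(g), drop = FALSE]

  # annotate: probes with effects sit at their (first) planted marker
  anchor <- rep(seq_len(ncol(g)), length.out = np)
  if (!is.null(eff)) {
    first <- eff[!duplicated(eff$probe), ]
    anchor[match(first$probe, probes)] <- match(first$marker, colnames(g))
  }
  ann <- data.frame(probe = probes, symbol = toupper(probes),
                    chr = geno$map$chr[anchor], mb = geno$map$mb[anchor])

  va <- va_add + config$var_strain
  truth <- list(
    probes = data.frame(probe = probes, va = va, ve = config$var_resid,
                        h2 = va / (va + 2 * config$var_resid)),
    effects = eff,
    strain_means = true_mean)
  list(expr = expr_matrix(means, ann,
                          replicates = list(values = repl,
                                            strain = strain_of)),
       truth = truth)
}

#' Simulate allele-specific read counts from F1 replicates
#'
#' Per SNP and replicate, read depth is negative-binomial and the
#' reference count is `Binomial(depth, theta)`.  With probability
#' `outlier_rate` a replicate's `theta` is shifted by `outlier_shift`,
#' emulating a contaminated library.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (an [allele_counts()] table) and `truth`
#'   (per-gene `theta` and the planted outlier replicates).
#' @export
simulate_ase_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim_seed(config, 2L)
  ng <- config$n_ase_genes
  theta <- rep_len(config$theta, ng)
  genes <- sprintf("gene%03d", seq_len(ng))
  grid <- expand.grid(snp = seq_len(config$snps_per_gene),
                      gene = seq_len(ng))
  nsnp <- nrow(grid)
  reps <- config$ase_replicates

  rec <- vector("list", nsnp)
  outliers <- list()
  for (i in seq_len(nsnp)) {
    gi <- grid$gene[i]
    depth <- stats::rnbinom(reps, size = config$depth_dispersion,
                            mu = config$depth_mean)
    th <- rep(theta[gi], reps)
    is_out <- stats::runif(reps) < config$outlier_rate
    th[is_out] <- pmin(pmax(th[is_out] + config$outlier_shift, 0.01), 0.99)
    ref <- stats::rbinom(reps, depth, th)
    pos <- 1000000L + grid$snp[i] * 500L
    rec[[i]] <- data.frame(
      gene = genes[gi], chrom = as.character(1L + (gi - 1L) %% 19L),
      pos = pos, ref_base = "A", alt_base = "G",
      replicate_id = sprintf("rep%d", seq_len(reps)),
      ref_count = ref, alt_count = depth - ref, tissue = config$tissue)
    if (any(is_out))
      outliers[[length(outliers) + 1L]] <-
        data.frame(gene = genes[gi], pos = pos,
                   replicate_id = sprintf("rep%d", which(is_out)))
  }
  counts <- allele_counts(do.call(rbind, rec))
  truth <- list(genes = data.frame(gene = genes, theta = theta),
                outliers = if (length(outliers))
                  do.call(rbind, outliers) else NULL)
  list(counts = counts, truth = truth)
}

#' Simulate strain-level phenotypes
#'
#' Same linear model as expression but one value per strain (no
#' replicates): `sum(effect * g) + Normal(0, trait_var)`.
#'
#' @param geno A [geno_matrix()].
#' @param config A [sim_config()]; traits without a row in `trait_effects`
#'   are pure noise.
#' @return A list with `pheno` (a [pheno_table()]) and `truth`.
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  sim_seed(config, 3L)
  g <- code_genotypes(geno)
  nt <- config$n_traits
  traits <- sprintf("trait%03d", seq_len(nt))
  genetic <- matrix(0, nt, nrow(g), dimnames = list(traits, rownames(g)))
  te <- config$trait_effects
  if (!is.null(te)) {
    te$trait <- as.character(te$trait)
    te$marker <- as.character(te$marker)
    if (!all(te$trait %in% traits)) stop("unknown trait in 'trait_effects'")
    if (!all(te$marker %in% colnames(g)))
      stop("unknown marker in 'trait_effects'")
    for (i in seq_len(nrow(te)))
      genetic[te$trait[i], ] <- genetic[te$trait[i], ] +
        te$effect[i] * g[, te$marker[i]]
  }
  vals <- genetic + matrix(stats::rnorm(nt * nrow(g), 0,
                                        sqrt(config$trait_var)),
                           nt, nrow(g))
  pheno <- pheno_table(vals, data.frame(record_id = traits,
                                        description = "simulated trait"))
  list(pheno = pheno, truth = list(effects = te))
}
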