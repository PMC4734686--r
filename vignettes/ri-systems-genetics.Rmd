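---
title: "Systems genetics in recombinant inbred panels with riqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems genetics in recombinant inbred panels with riqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riqtl)
```

## The setting

A biparental recombinant inbred (RI) panel — the BXD family derived from
C57BL/6J (*B*) and DBA/2J (*D*) is the canonical example — consists of
strains that are homozygous for either parental allele at essentially
every locus.  Because each strain is an immortal, replicable genome,
expression and phenotype measurements can be accumulated across
laboratories and years and mapped against a single shared genotype
matrix.  `riqtl` implements the analysis chain used in such studies:

1. **Heritability** of a trait from strain replicates.
2. **eQTL mapping**: single-marker genome scans with permutation-based
   genome-wide significance, 1.5-LOD support intervals, and cis/trans
   classification.
3. **Allele-specific expression (ASE)** calling from F1-hybrid read
   counts, the molecular validation of a cis eQTL.
4. **Partial-correlation networks** that remove the confounding effect of
   linkage disequilibrium around a controlled locus, plus module
   eigengene (PC1) signatures and top-correlate lists.
5. **Downstream screens** for transcripts and phenotypes putatively
   regulated by a target locus.

A synthetic-data module generates genotypes, expression, allele counts
and phenotypes with known ground truth, so the whole chain is testable
without any external download.

## Models and conventions

### Genotype coding

Calls are `B`/`D`/`H`/`U`.  For modelling, `B = -1` and `D = +1`, so a
positive additive effect means higher trait values with the *D*
(paternal, in BXD) allele — the sign convention used in published
additive-effect columns.  `U` is always excluded; `H` is excluded by
default (heterozygous calls in a fully inbred panel are usually
genotyping errors) or can be coded 0 via `het = "zero"`.

### Broad-sense heritability

For inbred strains with biological replicates,

$$H^2 = \frac{0.5\,V_A}{0.5\,V_A + V_E} = \frac{V_A}{V_A + 2 V_E},$$

where $V_A$ is the variance of strain means, $V_T$ the total variance
among subjects, and $V_E = V_T - V_A$.  Both variances use the unbiased
$n-1$ estimator; strain means are unweighted under unbalanced
replication (the simplest faithful reading of "variance of strain
means").  Two numerical choices matter:

* **Negative raw $V_E$.** With $n-1$ weighting, $V_T$ of pooled subjects
  can fall below $V_A$ (it always does when replicates are identical),
  so $V_E$ is clamped to zero before the ratio and the raw value is
  reported alongside for audit.
* **Estimator bias.** $V_A$ absorbs $\sigma^2_e/m$ for $m$ replicates and
  the clamp is one-sided, so $\hat H^2$ is biased upward; the bias grows
  with the ratio $\sigma^2_e / (m V_A)$.  This is a property of the
  published formula, not of the implementation; the synthetic defaults
  (below) were chosen so the bias is small relative to the recovery
  tolerance used in the tests.

### Genome scans

For a densely genotyped homozygous panel, single-marker regression
coincides with interval mapping at the markers, and peaks are reported at
markers, so the scan is an ordinary least-squares fit per marker with

$$\mathrm{LRS} = n \ln(\mathrm{RSS}_0/\mathrm{RSS}_1), \qquad
  \mathrm{LOD} = \mathrm{LRS}/(2 \ln 10).$$

The additive effect is the slope: half the D-minus-B class-mean
difference.  Degenerate cases are explicit: a constant trait gives LRS 0
everywhere; a marker that is monomorphic among usable strains (or has
fewer than 3 of them) yields a missing statistic, never a zero; a perfect
fit is reported at a configurable LOD cap (default 50) with a flag.

Genome-wide significance is the empirical $1-\alpha$ quantile (linear
interpolation) of the maximum LOD over permutations of strain labels —
5000 or more permutations is the conventional production setting, and the
package's own calibration runs use 1000 to keep the suite fast.  The
suggestive threshold defaults to $\alpha = 0.63$ (about one false
positive per genome scan) but is a parameter, since published figures
sometimes draw the suggestive line at $p < 0.3$ instead.

The 1.5-LOD support interval is the widest contiguous marker run around
the peak with LOD within `drop` of the maximum, extended half-way to the
first excluded flanking marker and truncated at chromosome ends.
Published interval bounds are printed in whole megabases without an
endpoint rule; the midpoint extension is symmetric and testable, which is
why it was chosen.  Peak ties break to the lowest genomic coordinate for
determinism.  A peak within 10 Mb of the measured gene on the same
chromosome (inclusive) is classified *cis*, otherwise *trans*.

### ASE calling

Per SNP, replicate allelic ratios $r = \mathrm{ref}/(\mathrm{ref} +
\mathrm{alt})$ are screened with Tukey fences
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$; quartiles use
linear interpolation (type 7), configurable because the named rule does
not pin down the quantile estimator.  "Concordant" means exactly "not
flagged by the IQR rule" — the source methods define no second criterion.
Counts of concordant replicates are summed and tested against a 1:1
expectation with a 1-df chi-square goodness-of-fit test (no continuity
correction; two-sided by construction).  SNPs below 10 merged reads are
dropped (degenerate chi-square guard; configurable and logged).
Benjamini–Hochberg q-values are computed within each tissue by default.
A gene is imbalanced when at least one SNP has $q < 0.1$ **and** allelic
fold difference $\max(r, 1-r)/\min(r, 1-r) > 1.25$, both strict.  The
fold is evaluated from the merged integer counts, which is algebraically
the same but exact at the 1.25 boundary (the ratio form of $r = 5/9$
exceeds 1.25 by one ulp).  Whether the published ">1.25 fold" means
allelic fold or parental expression fold is ambiguous; allelic fold is
the only reading computable from the quantities the ASE pipeline itself
produces, and is what the caller implements.

### Correlations, partial correlations, PC1

p-values come from $t = r\sqrt{\mathrm{df}/(1-r^2)}$.  The default is
the upper-tail probability of $|t|$ (a one-sided/magnitude convention):
it reproduces how strain-panel correlation databases pair $r$ with $p$
more closely than the two-sided value, and the two-sided convention is a
flag everywhere.  Partial correlation regresses both series on the
covariates (coded genotypes at the control markers, plus intercept) and
correlates residuals, with df $= n - 2 - k$; collinear covariates are
dropped by QR rank.  A series fully explained by the covariates returns
$r = 0$ (there is nothing left to correlate — correlating the
floating-point residual noise would be meaningless).  An empty covariate
set reduces exactly to the plain correlation.

Module signatures are the first principal component of the standardized
member submatrix with strains as observations (correlation-matrix PCA, so
probes with different dynamic ranges weigh equally); variance explained
is $\lambda_1 / \sum_i \lambda_i$ and the sign is oriented so the
signature correlates positively with its members on average.

### Downstream screens

A transcript is a candidate downstream target of a locus when its mean
expression exceeds 8 log2 units, its peak LOD exceeds 2 (both strict),
and the peak lies in a 4 Mb window overlapping the target locus.  "A 4 Mb
region overlapping the location of the target" is ambiguous; the default
is the minimal reading, a window of total width 4 Mb centred on the gene
(`window_style = "centered"`), with the wider `gene +/- 4 Mb` reading
available as `"flank"`.  Hits are annotated with their correlation
against the target ($p < 0.01$ flags significance).  Phenotype screens
reuse the same marker-regression engine (no separate mapper): traits
whose peak (LOD > 2) falls within 2 Mb of the target locus, and traits
correlated with the target expression at $p < 0.005$, reported as
`(record_id, r, n)`.

## What the synthetic data emulates

`sim_config()` fixes the simulated study conditions used across the test
suite:

* **Genotypes**: 60 strains, 5 chromosomes x 20 markers at 2.5 Mb
  spacing; along each chromosome genotypes follow a two-state Markov
  chain with flip probability 0.05 between adjacent markers, emulating
  the haplotype-block structure of an RI panel (only linkage structure
  matters to the stages under test, so no pedigree is simulated).  All
  calls are homozygous.
* **Expression**: replicate value $= \mu + \sum a\,g + $ strain deviate
  $+$ residual, with $\mu = 8$ log2 units, strain-level variance 0.4 and
  replicate-level variance 0.008 over 4 replicates.  These defaults
  emulate a strongly heritable, cis-modulated transcript measured with
  tight within-strain replication — the regime of the ASE-validated GST
  genes — and were fixed after the bias analysis above so that the
  $H^2$ estimator's inherent upward bias stays well inside the $\pm 0.05$
  recovery band at 60 strains x 4 replicates.
* **ASE counts**: per SNP and replicate, depth $\sim$ negative binomial
  (mean 200, dispersion 10; overdispersed depths are typical of RNA-seq)
  and reference count $\sim$ Binomial(depth, $\theta$), across 6
  replicates as in an F1 RNA-seq design; a configurable fraction of
  replicates has $\theta$ shifted (default +0.4), emulating a
  contaminated library that the IQR rule should catch.
* **Phenotypes**: the same linear model at strain level with residual
  variance 1, so a planted effect of 1 gives an effect-to-noise ratio
  $a/\sigma = 1$.

What it deliberately does **not** emulate: realistic BXD linkage maps and
marker density, allele-frequency distortion, non-normal trait
distributions, probe-level hybridization artifacts, reference-mapping
bias in ASE counts, and beta-binomial overdispersion of allelic ratios.
Green tests therefore certify the statistical machinery under its own
model assumptions, not robustness to every pathology of real data.

## Problem sizes used by the checks

The package's calibration and recovery runs use: 5000 null and 500
imbalanced SNPs for the ASE caller; 200 planted traits
($a/\sigma = 1$, 60 strains) and 1000 null traits with 1000-permutation
thresholds for the eQTL stage; 200 probes at 60 strains x 4 replicates
for heritability.  These sizes give Monte-Carlo errors comfortably below
the tolerances they are checked against (for example, the null
genome-wide exceedance rate at the 5% threshold has a binomial standard
error of about 0.7 percentage points at 1000 traits).

## Validation against published numbers

Two plain-text tables under `inst/extdata` carry published worked
numbers: merged B6/D2 read counts with p-values and allelic ratios for
GST-gene SNPs in B6xD2 F1 hybrids, and cis-eQTL peak LRS/LOD/additive
columns for five GST genes across panels.  The test suite recomputes the
ratios and chi-square p-values from the printed counts and checks the
LOD $=$ LRS$/(2\ln 10)$ identity on the BXD rows.  Three entries in the
published tables are internally inconsistent and the corresponding
assertions fail honestly rather than being loosened: one printed p-value
(3.02e-9) differs from any standard test applied to its own printed
counts (chi-square 2.97e-9), two p-values printed as "0.00E+00" have
counts implying p around 1e-9 and 1e-13, and one LRS/LOD pair deviates
from the identity by slightly more than rounding can explain (0.022).
Likewise the printed correlation anchor ($r = 0.6$, $n = 67$,
$p = 3.77\times 10^{-8}$) corresponds to an unrounded $r \approx 0.601$:
with $r = 0.6$ exactly, the one-sided p is $4.02\times 10^{-8}$.  The
one-sided convention is retained because it is decisively closer than
the two-sided alternative ($8.05\times 10^{-8}$).

## Worked example

```{r example}
cfg <- sim_config(seed = 42, n_probes = 5,
                  effects = data.frame(probe = "probe001",
                                       marker = "c3m10", effect = 0.6))
geno <- simulate_ri_genotypes(cfg)
sim <- simulate_expression(geno, cfg)

# heritability of every probe from its replicates
head(h2_scan(sim$expr), 3)

# genome scan + permutation threshold for the planted probe
scan <- marker_regression(sim$expr$values["probe001", ], geno)
peak <- find_peak(scan)
thr <- permutation_threshold(sim$expr$values["probe001", ], geno,
                             n_perm = 1000, seed = 1)
peak$lod
thr
lod_support_interval(scan, peak)

# ASE on simulated counts with a planted 0.35 ratio
acfg <- sim_config(seed = 7, n_ase_genes = 3, theta = 0.35)
calls <- ase_call(simulate_ase_counts(acfg)$counts)
calls$gene
```

## Known limitations

* Single-marker scans only: no interval mapping between markers, no
  multi-locus or epistasis models, no FDR across probes.
* The permutation engine assumes exchangeability of strains; kinship
  beyond the marker under test is not modelled.
* The ASE caller uses a pure binomial null; allelic ratios that are
  overdispersed across replicates beyond what the IQR filter removes
  will inflate significance.
* Literature correlations are consumed as a precomputed two-column
  table; computing them is out of scope.
* Reproduction of dataset-specific published LOD and $H^2$ values would
  require the original strain-level data and is not attempted; the
  validation rests on the worked tables and on synthetic ground truth.
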