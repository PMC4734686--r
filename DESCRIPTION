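Package: riqtl
Title: Systems Genetics for Recombinant Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for expression genetics in biparental
    recombinant inbred (RI) panels such as the BXD family.  Provides
    readers for GeneNetwork-style genotype files and tabular expression,
    phenotype and allele-count data; broad-sense heritability from strain
    replicates; single-marker genome scans with permutation-based
    genome-wide significance thresholds, 1.5-LOD support intervals and
    cis/trans classification; an allele-specific expression caller with
    interquartile-range replicate filtering, chi-square imbalance tests
    and Benjamini-Hochberg false discovery control; genotype-controlled
    partial-correlation networks with module eigengene (PC1) signatures;
    and rule-based screens for transcripts and phenotypes downstream of a
    target locus.  A synthetic-data module simulates RI genotypes,
    expression, allele counts and phenotypes with known ground truth so
    that every stage can be tested without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
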