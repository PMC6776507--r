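Package: asmscan
Title: Integration of Brain Allele-Specific Methylation with GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("ASM", "Scan Developers", email = "asmscan@example.org", role = c("aut", "cre"))
Description: Tools to identify disorder risk variants acting through brain
    allele-specific methylation (ASM). Merges and filters SNP-CpG meQTL
    catalogs from multiple studies and tissues, selects tagSNPs from a phased
    reference haplotype panel (LD r2), screens tagSNPs against case-control
    GWAS summary statistics under FDR (Storey q-values), Bonferroni and
    effective-number-of-tests corrections, tests set enrichment of
    sub-threshold risk variants among ASM SNPs, and integrates methylation
    direction with brain eQTL, histone-mark and subcortical-volume
    annotations to prioritize one putative causal SNP per LD block. Ships a
    synthetic-data generator with ground-truth manifests so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
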