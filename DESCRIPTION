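Package: cogset
Title: Gene-Set Enrichment Pipeline for Cognitive GWAS Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable inference chain from cohort genotype and phenotype
    data to cross-cohort gene-set enrichment evidence: single-SNP additive
    association, fixed-effect inverse-variance meta-analysis, LD-aware
    gene-based empirical P-values via multivariate-normal Monte Carlo,
    competitive running-sum gene-set enrichment with a permutation null and
    GSEA-style FDR, empirical validation against random gene sets, and
    Stouffer weighted-Z combination of enrichment evidence across cohorts.
    Includes a synthetic multi-cohort generator (LD-blocked genotypes via
    Gaussian-copula haplotypes, a latent-factor cognitive test battery, and
    a polygenic architecture concentrated in a designated gene set) so the
    whole pipeline is testable without external data, plus readers and
    writers for VCF dosages, PLINK bed/bim/fam, BED, GMT and summary TSVs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    GenomicRanges,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    metafor
Config/testthat/edition: 3
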