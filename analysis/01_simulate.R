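#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic study.
#
# Two cohorts of unrelated individuals genotyped on the same SNP panel:
# 300 genes across the autosomes, 2-4 common SNPs per gene with AR(1)
# within-gene LD, a 30-gene causal set carrying 15% of the latent trait
# variance, and a five-test battery loading 0.7 on the latent factor with
# age and sex nuisance effects. Everything downstream reads the files this
# script writes under results/data/.

suppressMessages(library(cogset))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_cohorts = 2, n_samples = c(800, 600), n_genes = 300,
  snps_per_gene = c(2, 4), ld_rho = 0.8, causal_set_size = 30,
  h2_set = 0.15, h2_background = 0.05, n_tests = 5,
  factor_loadings = 0.7, seed = 2026
)

ann <- make_gene_annotation(cfg)
sets <- make_gene_sets(ann, cfg)
write_gene_bed(ann$genes, file.path(out, "annotation.bed"))
write_gmt(sets, file.path(out, "gene_sets.gmt"))

for (k in 1:2) {
  gt <- simulate_genotypes(ann, cfg, k)
  ph <- simulate_phenotypes(gt, ann, sets$sets$causal, cfg, k)
  write_dosage_tsv(gt, file.path(out, sprintf("genotypes_cohort%d.tsv", k)))
  write_phenotype_tsv(ph, file.path(out, sprintf("phenotypes_cohort%d.tsv", k)))
  # also demonstrate the interchange formats on a small slice
  if (k == 1) {
    slice <- genotype_matrix(gt$dosage[1:50, 1:20], gt$snps[1:20, ],
                             gt$sample_ids[1:50])
    write_vcf_dosage(slice, file.path(out, "cohort1_slice.vcf"))
    write_plink(slice, file.path(out, "cohort1_slice"))
  }
  cat(sprintf("cohort %d: %d samples x %d SNPs, realized MAF range %.3f-%.3f\n",
              k, length(gt$sample_ids), nrow(gt$snps),
              min(colMeans(gt$dosage) / 2), max(colMeans(gt$dosage) / 2)))
}

cat(sprintf("annotation: %d genes, %d SNPs; causal set %d genes\n",
            nrow(ann$genes), nrow(ann$snps), length(sets$sets$causal)))
jsonlite::write_json(cogset:::unclass_deep(cfg),
                     file.path(out, "sim_config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
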