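#!/usr/bin/env Rscript
# Stage 3 -- per-cohort QC + single-SNP association, then IVW meta-analysis.
#
# QC drops SNPs on call rate, MAF and exact Hardy-Weinberg thresholds;
# association is an additive-model OLS of the residualized factor score on
# allele dosage; cohorts are pooled with fixed-effect inverse-variance
# weighting. Writes assoc_cohort<k>.tsv and meta.tsv under results/.

suppressMessages(library(cogset))

dat <- "results/data"
out <- "results"

assoc <- list()
for (k in 1:2) {
  gt <- read_dosage_tsv(file.path(dat, sprintf("genotypes_cohort%d.tsv", k)))
  sc <- read_scores_tsv(file.path(dat, sprintf("scores_cohort%d.tsv", k)))
  q <- qc_filter(gt, qc_thresholds())
  assoc[[k]] <- snp_association(q$genotypes, sc)
  write_summary_tsv(assoc[[k]], file.path(out, sprintf("assoc_cohort%d.tsv", k)))
  cat(sprintf("cohort %d: %d SNPs post-QC (%d removed: %s), min p = %.2e\n",
              k, nrow(assoc[[k]]), nrow(q$report),
              if (nrow(q$report)) paste(unique(q$report$reason), collapse = "/")
              else "none",
              min(assoc[[k]]$p)))
}

meta <- ivw_meta(assoc)
write_summary_tsv(meta, file.path(out, "meta.tsv"))
lambda <- median(meta$z^2) / qchisq(0.5, 1)
cat(sprintf("meta: %d SNPs, all k_studies=2: %s; min p = %.2e; lambda = %.3f\n",
            nrow(meta), all(meta$k_studies == 2), min(meta$p), lambda))
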