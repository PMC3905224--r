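test_that("annotation generation is deterministic and respects the layout", {
  cfg <- sim_config(n_genes = 50, seed = 42)
  a1 <- make_gene_annotation(cfg)
  a2 <- make_gene_annotation(cfg)
  expect_identical(a1, a2)
  expect_false(anyDuplicated(a1$genes$gene_id) > 0)
  expect_true(all(a1$genes$start <= a1$genes$end))
  # SNPs inside gene bodies, strictly increasing positions per chromosome
  g <- a1$genes[match(a1$snps$gene_id, a1$genes$gene_id), ]
  expect_true(all(a1$snps$position >= g$start & a1$snps$position <= g$end))
  for (chr in unique(a1$snps$chromosome)) {
    expect_false(is.unsorted(a1$snps$position[a1$snps$chromosome == chr],
                             strictly = TRUE))
  }
})

test_that("default gap keeps 50 kb windows disjoint; overlap mode crosses them", {
  cfg <- sim_config(n_genes = 44, seed = 5)
  ann <- make_gene_annotation(cfg)
  asg <- assign_snps(ann$snps, ann$genes, window_kb = 50)
  counts <- table(unlist(asg))
  expect_true(all(counts == 1)) # every SNP maps to exactly one gene
  expect_setequal(unlist(asg), ann$snps$snp_id)

  cfg_ov <- sim_config(n_genes = 44, overlap_mode = TRUE, seed = 5)
  ann_ov <- make_gene_annotation(cfg_ov)
  asg_ov <- assign_snps(ann_ov$snps, ann_ov$genes, window_kb = 50)
  counts_ov <- table(unlist(asg_ov))
  expect_true(any(counts_ov == 2))
  # brute-force interval check of the emitted coordinates
  multi <- names(counts_ov)[counts_ov == 2][1]
  pos <- ann_ov$snps$position[ann_ov$snps$snp_id == multi]
  chr <- ann_ov$snps$chromosome[ann_ov$snps$snp_id == multi]
  inside <- with(ann_ov$genes,
                 chromosome == chr & pos >= start - 50000 & pos <= end + 50000)
  expect_identical(sum(inside), 2L)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(gene_length_bp = 3, snps_per_gene = c(2, 5)),
               "configuration error")
  expect_error(sim_config(h2_set = 0.6, h2_background = 0.5))
  expect_error(sim_config(maf_range = c(0, 0.5)))
})

test_that("genotype simulation matches its LD and MAF targets", {
  cfg0 <- sim_config(n_samples = 2000, n_genes = 40, snps_per_gene = c(4, 4),
                     ld_rho = 0, seed = 11)
  ann <- make_gene_annotation(cfg0)
  gt <- simulate_genotypes(ann, cfg0, 1)
  expect_identical(gt$dosage, simulate_genotypes(ann, cfg0, 1)$dosage)
  expect_true(all(gt$dosage %in% 0:2))

  # ld_rho = 0: adjacent same-gene dosage correlations are near zero
  adj <- unlist(lapply(split(seq_len(nrow(gt$snps)), gt$snps$gene_id),
                       function(j) {
    sapply(seq_len(length(j) - 1), function(k) {
      cor(gt$dosage[, j[k]], gt$dosage[, j[k + 1]])
    })
  }))
  expect_lt(mean(abs(adj)), 0.05)

  # realized allele frequencies near the targets (binomial bound at n=2000)
  realized <- colMeans(gt$dosage) / 2
  expect_true(all(abs(realized - gt$snps$target_maf) < 0.03))
  expect_true(all(realized > 0))

  # LD decays with distance when ld_rho > 0
  cfg1 <- sim_config(n_samples = 2000, n_genes = 40, snps_per_gene = c(4, 4),
                     ld_rho = 0.9, seed = 11)
  gt1 <- simulate_genotypes(make_gene_annotation(cfg1), cfg1, 1)
  by_gene <- split(seq_len(nrow(gt1$snps)), gt1$snps$gene_id)
  r_adj <- mean(sapply(by_gene, function(j) {
    cor(gt1$dosage[, j[1]], gt1$dosage[, j[2]])
  }))
  r_far <- mean(sapply(by_gene, function(j) {
    cor(gt1$dosage[, j[1]], gt1$dosage[, j[4]])
  }))
  expect_gt(r_adj, r_far)
  expect_gt(r_adj, 0.4)
})

test_that("cohorts are independent draws and extra cohorts leave earlier ones alone", {
  cfg <- sim_config(n_cohorts = 2, n_samples = 300, n_genes = 20, seed = 3)
  ann <- make_gene_annotation(cfg)
  g1 <- simulate_genotypes(ann, cfg, 1)
  g2 <- simulate_genotypes(ann, cfg, 2)
  expect_false(identical(g1$dosage, g2$dosage))
  cfg3 <- sim_config(n_cohorts = 3, n_samples = 300, n_genes = 20, seed = 3)
  expect_identical(simulate_genotypes(ann, cfg3, 1)$dosage, g1$dosage)
})

test_that("null phenotypes give uniform association P-values", {
  cfg <- sim_config(n_samples = 500, n_genes = 125, snps_per_gene = c(4, 4),
                    h2_set = 0, h2_background = 0, seed = 21)
  ann <- make_gene_annotation(cfg)
  gt <- simulate_genotypes(ann, cfg, 1)
  sets <- make_gene_sets(ann, cfg)
  ph <- simulate_phenotypes(gt, ann, sets$sets$causal, cfg, 1)
  sc <- phenotype_scores(ph)
  ss <- snp_association(gt, sc)
  expect_identical(nrow(ss), 500L)
  expect_gt(ks.test(ss$p, "punif")$p.value, 0.01)
})

test_that("phenotype construction recovers its own generating parameters", {
  cfg <- sim_config(n_samples = 2000, n_genes = 100, causal_set_size = 20,
                    h2_set = 0.2, seed = 31)
  ann <- make_gene_annotation(cfg)
  gt <- simulate_genotypes(ann, cfg, 1)
  sets <- make_gene_sets(ann, cfg)
  ph <- simulate_phenotypes(gt, ann, sets$sets$causal, cfg, 1)
  # regression of the latent trait on the true causal genetic value: slope 1
  X <- gt$dosage[, gt$snps$gene_id %in% sets$sets$causal]
  # reconstruct the genetic value by refitting: latent_g regressed on the
  # causal dosages should explain ~h2_set of its variance
  fit <- lm(ph$latent_g ~ X)
  expect_lt(abs(summary(fit)$r.squared - cfg$h2_set), 0.05)
  slope <- coef(lm(ph$latent_g ~ fitted(fit)))[2]
  expect_lt(abs(slope - 1), 0.1)

  # loadings 1, no nuisance: tests perfectly correlated with latent g
  cfg1 <- sim_config(n_samples = 200, n_genes = 20, factor_loadings = 1,
                     beta_age = 0, beta_sex = 0, seed = 32)
  ann1 <- make_gene_annotation(cfg1)
  gt1 <- simulate_genotypes(ann1, cfg1, 1)
  ph1 <- simulate_phenotypes(gt1, ann1, ann1$genes$gene_id[1:5], cfg1, 1)
  expect_true(all(abs(apply(ph1$battery, 2, cor, y = ph1$latent_g) - 1) < 1e-12))

  expect_error(
    simulate_phenotypes(gt1, ann1, character(0),
                        sim_config(n_samples = 200, n_genes = 20,
                                   h2_set = 0.2, seed = 1), 1),
    "empty"
  )
})

test_that("gene sets have the stated sizes and hypergeometric decoy overlap", {
  cfg <- sim_config(n_genes = 100, causal_set_size = 50, seed = 9)
  ann <- make_gene_annotation(cfg)
  sets <- make_gene_sets(ann, cfg)
  expect_length(sets$sets$causal, 50)
  expect_false(anyDuplicated(sets$sets$causal) > 0)
  expect_identical(make_gene_sets(ann, cfg)$sets$decoy, sets$sets$decoy)
  expect_length(sets$sets$all_genes, 100)

  # overlap of independent decoys with the causal set follows the exact
  # hypergeometric law: compare mean over 300 draws with its expectation
  ov <- sapply(1:300, function(i) {
    length(intersect(make_gene_sets(ann, cfg, decoy_key = i)$sets$decoy,
                     sets$sets$causal))
  })
  m <- 50 * 50 / 100                      # exact hypergeometric mean
  v <- 50 * (50 / 100) * (50 / 100) * (50 / 99) # exact variance
  expect_lt(abs(mean(ov) - m), 4 * sqrt(v / 300))
})

test_that("missing-data injection respects the configured rate", {
  cfg <- sim_config(n_samples = 500, n_genes = 30, missing_rate = 0.05,
                    seed = 13)
  ann <- make_gene_annotation(cfg)
  gt <- simulate_genotypes(ann, cfg, 1)
  expect_lt(abs(mean(is.na(gt$dosage)) - 0.05), 0.01)
})
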