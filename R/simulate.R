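#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the synthetic multi-cohort generator: genome layout
#' (genes, SNP density, inter-gene gaps), LD structure (AR(1) latent
#' correlation between adjacent SNPs within a gene), allele-frequency range,
#' the polygenic architecture (a designated causal gene set carrying
#' `h2_set` of phenotypic variance over an `h2_background` polygenic
#' background), and the cognitive test battery driven by a single latent
#' factor with age and sex nuisance effects.
#'
#' Defaults emulate common-variant cohorts of unrelated individuals: common
#' SNPs only (MAF in `[0.05, 0.5]`), moderate within-gene LD
#' (`ld_rho = 0.8`), genes far enough apart (150 kb) that the default
#' 50 kb assignment windows never overlap, and a battery of five tests with
#' loadings 0.7 on the latent factor.
#'
#' @param n_cohorts number of independent cohorts.
#' @param n_samples samples per cohort (recycled to `n_cohorts`).
#' @param n_genes number of autosomal genes laid across chromosomes 1-22.
#' @param snps_per_gene integer length-2 `(min, max)` SNPs per gene.
#' @param gene_length_bp gene body length in base pairs.
#' @param gap_bp gap between consecutive gene bodies on a chromosome.
#' @param overlap_mode if `TRUE`, the second gene of each chromosome is
#'   placed within 50 kb of the first so one SNP can map to two genes.
#' @param ld_rho AR(1) latent haplotype correlation between adjacent SNPs,
#'   in `[0, 1)`; pairwise latent correlation decays as `ld_rho^|i-j|`.
#' @param maf_range length-2 range of target minor-allele frequencies,
#'   within `(0, 0.5]`.
#' @param causal_set_size number of genes in the causal ("true" enriched) set.
#' @param h2_set fraction of phenotypic variance of the latent trait
#'   explained by causal-set SNPs.
#' @param h2_background fraction explained by all background (non-causal-set)
#'   SNPs; `h2_set + h2_background < 1`.
#' @param n_tests number of tests in the cognitive battery.
#' @param factor_loadings per-test loading on the latent factor, in `(0, 1]`
#'   (recycled to `n_tests`).
#' @param beta_age,beta_sex nuisance effects of age (per year, on the test
#'   scale) and sex (male-female difference) added to every test.
#' @param age_range length-2 integer range of ages (discrete uniform).
#' @param missing_rate fraction of dosages set missing (off by default;
#'   exercises QC call-rate filtering).
#' @param seed master seed; all randomness is derived from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cohorts = 1,
                       n_samples = 1000,
                       n_genes = 200,
                       snps_per_gene = c(2L, 5L),
                       gene_length_bp = 30000,
                       gap_bp = 150000,
                       overlap_mode = FALSE,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal_set_size = 20,
                       h2_set = 0,
                       h2_background = 0,
                       n_tests = 5,
                       factor_loadings = 0.7,
                       beta_age = -0.02,
                       beta_sex = 0.1,
                       age_range = c(40L, 79L),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_samples = rep_len(as.integer(n_samples), n_cohorts),
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    gene_length_bp = as.integer(gene_length_bp),
    gap_bp = as.integer(gap_bp),
    overlap_mode = isTRUE(overlap_mode),
    ld_rho = ld_rho,
    maf_range = maf_range,
    causal_set_size = as.integer(causal_set_size),
    h2_set = h2_set,
    h2_background = h2_background,
    n_tests = as.integer(n_tests),
    factor_loadings = rep_len(factor_loadings, n_tests),
    beta_age = beta_age,
    beta_sex = beta_sex,
    age_range = as.integer(age_range),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_cohorts >= 1, all(cfg$n_samples >= 2),
    cfg$n_genes >= 1,
    length(cfg$snps_per_gene) == 2,
    cfg$snps_per_gene[1] >= 1, cfg$snps_per_gene[1] <= cfg$snps_per_gene[2],
    cfg$ld_rho >= 0, cfg$ld_rho < 1,
    length(cfg$maf_range) == 2,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    cfg$causal_set_size >= 1, cfg$causal_set_size <= cfg$n_genes,
    cfg$h2_set >= 0, cfg$h2_background >= 0,
    cfg$h2_set + cfg$h2_background < 1,
    cfg$n_tests >= 1,
    all(cfg$factor_loadings > 0), all(cfg$factor_loadings <= 1),
    cfg$missing_rate >= 0, cfg$missing_rate < 1
  )
  if (cfg$gene_length_bp < cfg$snps_per_gene[2]) {
    stop("configuration error: gene_length_bp too small to place ",
         cfg$snps_per_gene[2], " distinct SNP positions")
  }
  if (cfg$gap_bp < 1) {
    stop("configuration error: gap_bp must be positive")
  }
  invisible(cfg)
}

#' Lay out a synthetic gene annotation and SNP map
#'
#' Genes are placed sequentially along chromosomes 1-22 (round-robin),
#' separated by `gap_bp`; SNP positions are drawn uniformly inside each gene
#' body. With the default 150 kb gap and 50 kb assignment windows every SNP
#' maps to exactly one gene; `overlap_mode` instead places the second gene of
#' each chromosome 40 kb after the end of the first so that windows overlap
#' and a SNP between them maps to both.
#'
#' @param config a [sim_config()].
#' @return A list with `genes` (data.frame: `gene_id`, `chromosome`, `start`,
#'   `end`, 1-based inclusive) and `snps` (data.frame: `snp_id`,
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`, `target_maf`,
#'   `gene_id` of the body the SNP was placed in).
#' @export
make_gene_annotation <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, "annotation"), {
    n_chr <- min(22L, config$n_genes)
    chr_of <- rep_len(seq_len(n_chr), config$n_genes)
    chr_of <- sort(chr_of)
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chromosome = chr_of,
      start = NA_integer_, end = NA_integer_
    )
    for (chr in seq_len(n_chr)) {
      idx <- which(chr_of == chr)
      pos <- 1L
      for (j in seq_along(idx)) {
        if (config$overlap_mode && j == 2) {
          # place 40 kb downstream of gene 1 so +/-50 kb windows overlap
          pos <- genes$end[idx[1]] + 40000L
        }
        genes$start[idx[j]] <- pos
        genes$end[idx[j]] <- pos + config$gene_length_bp - 1L
        pos <- genes$end[idx[j]] + config$gap_bp + 1L
      }
    }
    k_range <- seq.int(config$snps_per_gene[1], config$snps_per_gene[2])
    k <- if (length(k_range) == 1) {
      rep(k_range, config$n_genes)
    } else {
      sample(k_range, config$n_genes, replace = TRUE)
    }
    snp_rows <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      offs <- sort(sample.int(config$gene_length_bp, k[i]))
      snp_rows[[i]] <- data.frame(
        chromosome = genes$chromosome[i],
        position = genes$start[i] + offs - 1L,
        target_maf = stats::runif(k[i], config$maf_range[1], config$maf_range[2]),
        gene_id = genes$gene_id[i]
      )
    }
    snps <- do.call(rbind, snp_rows)
    snps <- snps[order(snps$chromosome, snps$position), ]
    # overlap_mode can duplicate a position across the two nearby gene bodies;
    # nudge duplicates to keep positions strictly increasing per chromosome
    dup <- duplicated(paste(snps$chromosome, snps$position))
    while (any(dup)) {
      snps$position[dup] <- snps$position[dup] + 1L
      snps <- snps[order(snps$chromosome, snps$position), ]
      dup <- duplicated(paste(snps$chromosome, snps$position))
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, nrow(snps), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    snps$ref_allele <- ref
    snps$alt_allele <- unname(alt)
    snps$snp_id <- sprintf("rs%06d", seq_len(nrow(snps)))
    rownames(snps) <- NULL
    snps <- snps[, c("snp_id", "chromosome", "position", "ref_allele",
                     "alt_allele", "target_maf", "gene_id")]
    list(genes = genes, snps = snps)
  })
}

#' Construct a genotype matrix object
#'
#' @param dosage numeric samples x SNPs matrix with values in `[0, 2]`
#'   (NA = missing).
#' @param snps SNP map data.frame with at least `snp_id`, `chromosome`,
#'   `position`, `ref_allele`, `alt_allele`.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, sample_ids) {
  stopifnot(
    is.matrix(dosage),
    nrow(dosage) == length(sample_ids),
    ncol(dosage) == nrow(snps),
    !anyDuplicated(snps$snp_id),
    !anyDuplicated(sample_ids)
  )
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  for (chr in unique(snps$chromosome)) {
    p <- snps$position[snps$chromosome == chr]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("SNP positions must be strictly increasing within a chromosome")
    }
  }
  dimnames(dosage) <- list(sample_ids, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$sample_ids), "samples x",
      nrow(x$snps), "SNPs\n")
  invisible(x)
}

# AR(1) latent Gaussian haplotypes for one gene: n_hap x n_snp matrix.
ar1_latent <- function(n_hap, n_snp, rho) {
  z <- matrix(stats::rnorm(n_hap * n_snp), n_hap, n_snp)
  if (rho > 0 && n_snp > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:n_snp) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

#' Simulate one cohort's genotypes with within-gene LD
#'
#' Each individual is the sum of two haplotypes. Haplotypes are generated per
#' gene by thresholding a latent Gaussian with AR(1) correlation
#' `ld_rho^|i-j|` at the quantile matching each SNP's target minor-allele
#' frequency (a Gaussian-copula construction), so LD decays with SNP distance
#' and vanishes between genes. Cohorts are independent draws from the same
#' process, seeded by `derive_seed(seed, "cohort<k>")`.
#'
#' @param annotation output of [make_gene_annotation()].
#' @param config the [sim_config()].
#' @param cohort_index which cohort (1-based).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(annotation, config, cohort_index = 1L) {
  validate_sim_config(config)
  stopifnot(cohort_index >= 1, cohort_index <= config$n_cohorts)
  n <- config$n_samples[cohort_index]
  snps <- annotation$snps
  seed <- derive_seed(config$seed, paste0("cohort", cohort_index))
  withr::with_seed(seed, {
    dosage <- matrix(0, n, nrow(snps))
    for (g in unique(snps$gene_id)) {
      j <- which(snps$gene_id == g)
      thr <- stats::qnorm(snps$target_maf[j])
      h1 <- sweep(ar1_latent(n, length(j), config$ld_rho), 2, thr, "<")
      h2 <- sweep(ar1_latent(n, length(j), config$ld_rho), 2, thr, "<")
      dosage[, j] <- h1 + h2
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(dosage)) < config$missing_rate
      dosage[miss] <- NA_real_
    }
    ids <- sprintf("C%d_S%05d", cohort_index, seq_len(n))
    genotype_matrix(dosage, snps, ids)
  })
}

#' Simulate a latent-factor cognitive test battery
#'
#' The latent trait is `g = g_set + g_bg + e`: `g_set` is a weighted sum of
#' causal-set SNP dosages (weights drawn standard normal) rescaled to sample
#' variance `h2_set`; `g_bg` the analogous background-SNP contribution at
#' `h2_background`; `e` Gaussian residual making `var(g) = 1`. Each battery
#' test is `loading_t * g + sqrt(1 - loading_t^2) * noise + beta_age * age +
#' beta_sex * sex`, with age discrete-uniform on `age_range` and sex
#' Bernoulli(0.5).
#'
#' @param genotypes a [genotype_matrix()] for the cohort.
#' @param annotation output of [make_gene_annotation()].
#' @param causal_set character vector of causal gene ids (must exist in the
#'   annotation; may be empty only if `h2_set = 0`).
#' @param config the [sim_config()].
#' @param cohort_index used to derive the phenotype seed.
#' @return A list: `battery` (samples x tests matrix), `age`, `sex` (0/1),
#'   `latent_g`, and `sample_ids`.
#' @export
simulate_phenotypes <- function(genotypes, annotation, causal_set, config,
                                cohort_index = 1L) {
  validate_sim_config(config)
  if (config$h2_set > 0 && length(causal_set) == 0) {
    stop("causal set is empty but h2_set > 0")
  }
  if (!all(causal_set %in% annotation$genes$gene_id)) {
    stop("causal_set contains genes absent from the annotation")
  }
  n <- length(genotypes$sample_ids)
  snp_gene <- genotypes$snps$gene_id
  causal_cols <- which(snp_gene %in% causal_set)
  bg_cols <- setdiff(seq_along(snp_gene), causal_cols)
  seed <- derive_seed(config$seed, paste0("phenotype", cohort_index))
  withr::with_seed(seed, {
    scaled_score <- function(cols, h2) {
      if (h2 <= 0 || length(cols) == 0) return(numeric(n))
      X <- genotypes$dosage[, cols, drop = FALSE]
      X[is.na(X)] <- 0
      raw <- drop(X %*% stats::rnorm(length(cols)))
      v <- stats::var(raw)
      if (v < .Machine$double.eps) return(numeric(n))
      (raw - mean(raw)) / sqrt(v) * sqrt(h2)
    }
    g_set <- scaled_score(causal_cols, config$h2_set)
    g_bg <- scaled_score(bg_cols, config$h2_background)
    resid_var <- 1 - config$h2_set - config$h2_background
    g <- g_set + g_bg + stats::rnorm(n, sd = sqrt(resid_var))
    age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    sex <- stats::rbinom(n, 1, 0.5)
    battery <- matrix(NA_real_, n, config$n_tests,
                      dimnames = list(genotypes$sample_ids,
                                      paste0("test_", seq_len(config$n_tests))))
    for (t in seq_len(config$n_tests)) {
      lam <- config$factor_loadings[t]
      battery[, t] <- lam * g + sqrt(1 - lam^2) * stats::rnorm(n) +
        config$beta_age * age + config$beta_sex * sex
    }
    list(battery = battery, age = age, sex = sex, latent_g = g,
         sample_ids = genotypes$sample_ids)
  })
}

#' Build the candidate gene-set collection for a simulated genome
#'
#' Emits three sets mirroring a candidate-list study design: the causal set
#' (the genes carrying `h2_set`), a size-matched random decoy drawn from all
#' genes (so its overlap with the causal set is hypergeometric), and the
#' full-genome set.
#'
#' @param annotation output of [make_gene_annotation()].
#' @param config the [sim_config()].
#' @param decoy_key optional suffix varied to draw independent decoys.
#' @return A list of class `gene_set_collection`: named `sets` (character
#'   vectors of gene ids) and parallel `descriptions`.
#' @export
make_gene_sets <- function(annotation, config, decoy_key = "") {
  validate_sim_config(config)
  gene_ids <- annotation$genes$gene_id
  causal <- withr::with_seed(derive_seed(config$seed, "causal_set"),
                             sort(sample(gene_ids, config$causal_set_size)))
  decoy <- withr::with_seed(
    derive_seed(config$seed, paste0("decoy_set", decoy_key)),
    sort(sample(gene_ids, config$causal_set_size))
  )
  gene_set_collection(
    sets = list(causal = causal, decoy = decoy, all_genes = gene_ids),
    descriptions = c(
      causal = "genes carrying the simulated causal variance",
      decoy = "size-matched random decoy set",
      all_genes = "every simulated gene"
    )
  )
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions named character vector (defaults to empty strings).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(sets[[nm]])) {
      stop("gene set '", nm, "' contains duplicate gene ids")
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", length(x$sets), "sets:\n")
  for (nm in names(x$sets)) {
    cat("  ", nm, ": ", length(x$sets[[nm]]), " genes\n", sep = "")
  }
  invisible(x)
}
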