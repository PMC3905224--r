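#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditioning on the observed
#' allele counts, the P-value is the sum of the probabilities of every
#' heterozygote count (same parity as the minor-allele count) whose
#' conditional probability does not exceed that of the observed
#' configuration. Computed in log space so small counts and extreme
#' departures are handled exactly.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return The exact two-sided P-value.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25) # balanced: large P
#' hwe_exact_test(50, 0, 50)  # no heterozygotes: tiny P
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_a <- 2 * n_aa + n_Aa            # allele 'a' count
  n_minor <- min(n_a, 2 * n - n_a)  # condition on the minor allele count
  if (n_minor == 0) return(1.0)     # monomorphic: single attainable config
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(h) under the conditional (fixed allele counts) distribution
  logp <- lfactorial(n) +
    lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n) +
    hets * log(2) -
    lfactorial((n_minor - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (n_minor + hets) / 2)
  p_obs <- logp[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count has impossible parity")
  p <- sum(exp(logp[logp <= p_obs + 1e-10]))
  min(1, p)
}

#' QC thresholds for per-cohort SNP filtering
#'
#' Defaults follow common GWAS practice for genotyped arrays: SNP call rate
#' above 0.98, minor allele frequency above 0.01, Hardy-Weinberg exact
#' P above 0.001; imputed SNPs additionally require an imputation quality
#' score above 0.3 and MAF above 0.005.
#'
#' @param call_rate_min,maf_min,hwe_p_min,imputation_quality_min,imputed_maf_min
#'   thresholds in `[0, 1]`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.98, maf_min = 0.01,
                          hwe_p_min = 0.001, imputation_quality_min = 0.3,
                          imputed_maf_min = 0.005) {
  th <- list(call_rate_min = call_rate_min, maf_min = maf_min,
             hwe_p_min = hwe_p_min,
             imputation_quality_min = imputation_quality_min,
             imputed_maf_min = imputed_maf_min)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Filter a genotype matrix on QC thresholds
#'
#' Removes SNPs failing call rate, MAF or Hardy-Weinberg thresholds. HWE is
#' computed on hard calls (rounded dosages) and only for SNPs flagged as
#' directly genotyped (`snps$genotyped`, if present; otherwise all). The
#' imputation-quality and imputed-MAF filters apply only when the SNP map
#' carries a `quality` column (for SNPs not flagged genotyped).
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list: `genotypes` (filtered matrix) and `report` (data.frame
#'   `snp_id`, `reason` for every removed SNP; reasons comma-joined).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  D <- genotypes$dosage
  snps <- genotypes$snps
  m <- ncol(D)
  call_rate <- colMeans(!is.na(D))
  eaf <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  genotyped <- if ("genotyped" %in% names(snps)) snps$genotyped else rep(TRUE, m)
  quality <- if ("quality" %in% names(snps)) snps$quality else rep(NA_real_, m)

  reasons <- vector("list", m)
  for (j in seq_len(m)) {
    why <- character()
    if (call_rate[j] < thresholds$call_rate_min) why <- c(why, "call_rate")
    if (genotyped[j]) {
      if (is.na(maf[j]) || maf[j] < thresholds$maf_min) why <- c(why, "maf")
      hard <- round(D[, j])
      cnt <- c(sum(hard == 0, na.rm = TRUE), sum(hard == 1, na.rm = TRUE),
               sum(hard == 2, na.rm = TRUE))
      if (sum(cnt) >= 1 &&
          hwe_exact_test(cnt[1], cnt[2], cnt[3]) < thresholds$hwe_p_min) {
        why <- c(why, "hwe")
      }
    } else {
      if (!is.na(quality[j]) && quality[j] < thresholds$imputation_quality_min) {
        why <- c(why, "quality")
      }
      if (is.na(maf[j]) || maf[j] < thresholds$imputed_maf_min) {
        why <- c(why, "imputed_maf")
      }
    }
    reasons[[j]] <- why
  }
  fail <- lengths(reasons) > 0
  report <- data.frame(
    snp_id = snps$snp_id[fail],
    reason = vapply(reasons[fail], paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  if (all(fail)) {
    stop("no SNP passes QC; consider relaxing the thresholds")
  }
  keep <- which(!fail)
  out <- genotype_matrix(D[, keep, drop = FALSE],
                         snps[keep, , drop = FALSE],
                         genotypes$sample_ids)
  list(genotypes = out, report = report)
}

#' Single-SNP additive association scan
#'
#' Per SNP, ordinary least squares of the phenotype on the allele dosage plus
#' covariates (additive model). Implemented by projecting the covariates out
#' of phenotype and dosages once (Frisch-Waugh) and running the residual
#' regressions vectorized. Missing dosages are mean-imputed per SNP.
#' Monomorphic SNPs are emitted with `beta = 0`, `p = 1` and flagged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype named numeric vector aligned to (a superset of) the
#'   genotype samples by name; unnamed vectors must match the sample order.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (samples x q), aligned like `phenotype`.
#' @return A `summary_stats` data.frame: `snp_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `z`, `p`, `n`,
#'   plus `log10p` (kept alongside `p` to survive extreme signals) and a
#'   `monomorphic` flag.
#' @export
snp_association <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- genotypes$sample_ids
  y <- if (!is.null(names(phenotype))) {
    if (!all(ids %in% names(phenotype))) {
      stop("phenotype missing for some genotyped samples")
    }
    phenotype[ids]
  } else {
    stopifnot(length(phenotype) == length(ids))
    phenotype
  }
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == length(ids))
    if (qr(cbind(1, C))$rank < ncol(C) + 1) {
      stop("covariate matrix (with intercept) is rank deficient")
    }
  }
  ok <- !is.na(y)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  y <- y[ok]
  n <- length(y)
  D <- genotypes$dosage[ok, , drop = FALSE]
  # per-SNP mean imputation of missing dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  X0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C[ok, , drop = FALSE])
  q <- ncol(X0)
  qrX <- qr(X0)
  ry <- stats::residuals(stats::lm.fit(X0, y))
  RD <- D - qr.fitted(qrX, D)
  Sxx <- colSums(RD^2)
  Sxy <- drop(crossprod(RD, ry))
  Syy <- sum(ry^2)
  df <- n - q - 1
  mono <- Sxx < .Machine$double.eps * n
  beta <- ifelse(mono, 0, Sxy / Sxx)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / df / Sxx))
  tstat <- ifelse(mono, 0, beta / se)
  logp <- stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE) + log(2)
  p <- ifelse(mono, 1, pmin(1, exp(logp)))
  z <- sign(tstat) * abs(stats::qnorm(logp - log(2), log.p = TRUE))
  eaf <- colMeans(D) / 2
  out <- data.frame(
    snp_id = genotypes$snps$snp_id,
    chr = genotypes$snps$chromosome,
    pos = genotypes$snps$position,
    effect_allele = genotypes$snps$alt_allele,
    other_allele = genotypes$snps$ref_allele,
    eaf = eaf,
    beta = beta,
    se = se,
    z = ifelse(mono, 0, z),
    p = p,
    n = n,
    log10p = ifelse(mono, 0, logp / log(10)),
    monomorphic = mono,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}
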