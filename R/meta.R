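#' Fixed-effect inverse-variance meta-analysis of SNP summary statistics
#'
#' Classical IVW pooling across cohorts: per SNP, weights `w_i = 1/se_i^2`,
#' pooled `beta = sum(w_i beta_i) / sum(w_i)`, `se = 1/sqrt(sum(w_i))`,
#' `z = beta/se` and a two-sided normal P. SNPs are matched by id across
#' cohorts. Effect alleles are harmonized to the first cohort reporting the
#' SNP: a cohort reporting the swapped allele pair has its beta sign and
#' allele frequency flipped; a cohort reporting the opposite strand is
#' re-complemented when the SNP is not strand-ambiguous; an irreconcilable
#' (or ambiguous-strand mismatching) allele pair drops the SNP with a
#' warning. A single cohort passes through with `k_studies = 1` (the same
#' beta and se; z and P recomputed on the normal scale).
#'
#' @param per_cohort list of `summary_stats` data.frames
#'   (see [snp_association()]); `effect_allele`, `other_allele`, `beta`,
#'   `se`, `p`, `n` are required per SNP.
#' @return A `meta_result` data.frame with the summary-stat columns plus
#'   `k_studies`.
#' @export
ivw_meta <- function(per_cohort) {
  stopifnot(is.list(per_cohort), length(per_cohort) >= 1)
  per_cohort <- lapply(per_cohort, as.data.frame)
  ref <- NULL # per-SNP reference alleles: first cohort reporting the SNP
  for (s in per_cohort) {
    add <- s[!(s$snp_id %in% ref$snp_id),
             c("snp_id", "chr", "pos", "effect_allele", "other_allele")]
    ref <- rbind(ref, add)
  }
  rownames(ref) <- ref$snp_id
  k <- integer(nrow(ref)); sw <- swb <- numeric(nrow(ref))
  eaf_acc <- n_acc <- numeric(nrow(ref))
  min_se <- rep(Inf, nrow(ref))
  dropped <- character()
  names(k) <- ref$snp_id
  comp <- function(a) chartr("ACGT", "TGCA", a)
  for (s in per_cohort) {
    i <- match(s$snp_id, ref$snp_id)
    ambiguous <- ref$effect_allele[i] == comp(ref$other_allele[i])
    same <- s$effect_allele == ref$effect_allele[i] &
      s$other_allele == ref$other_allele[i]
    flipped <- s$effect_allele == ref$other_allele[i] &
      s$other_allele == ref$effect_allele[i]
    # opposite-strand reports, resolvable only for non-ambiguous SNPs
    same <- same | (!ambiguous & !same & !flipped &
                      comp(s$effect_allele) == ref$effect_allele[i] &
                      comp(s$other_allele) == ref$other_allele[i])
    flipped <- flipped | (!ambiguous & !same & !flipped &
                            comp(s$effect_allele) == ref$other_allele[i] &
                            comp(s$other_allele) == ref$effect_allele[i])
    bad <- !(same | flipped)
    if (any(bad)) {
      dropped <- union(dropped, s$snp_id[bad])
    }
    use <- (same | flipped) & is.finite(s$se) & s$se > 0
    beta <- ifelse(flipped, -s$beta, s$beta)
    eaf <- ifelse(flipped, 1 - s$eaf, s$eaf)
    w <- 1 / s$se^2
    ii <- i[use]
    k[ii] <- k[ii] + 1L
    sw[ii] <- sw[ii] + w[use]
    swb[ii] <- swb[ii] + (w * beta)[use]
    eaf_acc[ii] <- eaf_acc[ii] + (s$n * eaf)[use]
    n_acc[ii] <- n_acc[ii] + s$n[use]
    min_se[ii] <- pmin(min_se[ii], s$se[use])
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped),
            " SNP(s) with irreconcilable allele pairs: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  keep <- k >= 1 & !(ref$snp_id %in% dropped)
  beta <- swb[keep] / sw[keep]
  se <- 1 / sqrt(sw[keep])
  z <- beta / se
  logp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  out <- data.frame(
    snp_id = ref$snp_id[keep],
    chr = ref$chr[keep],
    pos = ref$pos[keep],
    effect_allele = ref$effect_allele[keep],
    other_allele = ref$other_allele[keep],
    eaf = eaf_acc[keep] / n_acc[keep],
    beta = beta,
    se = se,
    z = z,
    p = pmin(1, exp(logp)),
    n = n_acc[keep],
    log10p = logp / log(10),
    k_studies = k[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("meta_result", "summary_stats", "data.frame")
  out
}
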