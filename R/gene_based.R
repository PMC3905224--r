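#' Assign SNPs to genes with flanking windows
#'
#' A SNP belongs to every gene whose body, extended by `window_kb` kilobases
#' on each side, contains its position (both window ends inclusive). Genes
#' without any SNP are absent from the mapping.
#'
#' @param snps data.frame with `snp_id`, `chromosome`, `position`.
#' @param genes data.frame with `gene_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @param window_kb flanking window in kb on each side (default 50).
#' @return A named list mapping `gene_id` to the character vector of its
#'   SNP ids, ordered by position; attribute `window_kb` records the window.
#' @export
assign_snps <- function(snps, genes, window_kb = 50) {
  stopifnot(window_kb >= 0, !anyDuplicated(genes$gene_id))
  w <- as.integer(round(window_kb * 1000))
  out <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    s <- snps[snps$chromosome == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    s <- s[order(s$position), , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = s$position, width = 1),
      IRanges::IRanges(start = pmax(1L, g$start - w), end = g$end + w)
    )
    if (length(hits) == 0) next
    by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    for (k in names(by_gene)) {
      out[[g$gene_id[as.integer(k)]]] <- s$snp_id[by_gene[[k]]]
    }
  }
  if (length(out) == 0) warning("no SNP fell inside any gene window")
  out <- out[intersect(genes$gene_id, names(out))]
  attr(out, "window_kb") <- window_kb
  out
}

#' Pairwise LD (dosage correlation) matrix for a set of SNPs
#'
#' Pearson correlation of mean-imputed dosages, repaired to positive
#' semi-definiteness by clipping eigenvalues at `1e-6` and rescaling back to
#' unit diagonal. The analysis cohort's own genotypes are the LD reference.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids SNPs to correlate (must be present, non-constant).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(genotypes, snp_ids) {
  stopifnot(length(snp_ids) >= 1)
  missing_ids <- setdiff(snp_ids, genotypes$snps$snp_id)
  if (length(missing_ids)) {
    stop("SNPs absent from genotypes: ", paste(missing_ids, collapse = ", "))
  }
  D <- genotypes$dosage[, snp_ids, drop = FALSE]
  stopifnot(nrow(D) >= 2)
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  v <- apply(D, 2, stats::var)
  if (any(v < .Machine$double.eps)) {
    stop("zero-variance SNP(s): ",
         paste(snp_ids[v < .Machine$double.eps], collapse = ", "))
  }
  R <- stats::cor(D)
  repair_correlation(R)
}

# Clip eigenvalues at eps and rescale to a unit-diagonal correlation matrix.
repair_correlation <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < eps) {
    lam <- pmax(e$values, eps)
    R <- e$vectors %*% (lam * t(e$vectors))
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
  }
  R
}

#' LD-corrected gene-based empirical P-value
#'
#' The gene statistic is the sum of squared SNP Z-scores,
#' `S = sum(z_i^2)`. Its null distribution accounts for both the number of
#' SNPs and their LD by Monte Carlo: draws `u ~ MVN(0, ld)` give null
#' statistics `S* = sum(u^2)`, and the empirical P is
#' `(1 + #\{S* >= S\}) / (B + 1)` (add-one correction, so P is never 0).
#' The simulation budget escalates through `schedule` while the number of
#' null exceedances is below 100, so extreme genes get more draws.
#'
#' @param z_scores numeric vector of per-SNP Z-scores for one gene.
#' @param ld LD correlation matrix, `length(z_scores)` square.
#' @param schedule increasing Monte-Carlo sizes; escalation stops at the
#'   last entry (the cap).
#' @param seed integer seed for the draws.
#' @return A list: `stat`, `p`, `n_sims`, `n_snps`.
#' @export
#' @examples
#' gene_empirical_p(1.96, matrix(1, 1, 1), schedule = 1e4, seed = 1)$p
gene_empirical_p <- function(z_scores, ld,
                             schedule = c(1e3, 1e4, 1e5), seed = 1L) {
  m <- length(z_scores)
  stopifnot(m >= 1, is.matrix(ld), nrow(ld) == m, ncol(ld) == m)
  S <- sum(z_scores^2)
  e <- eigen(repair_correlation(ld), symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("LD matrix not PSD after repair")
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), m)
  hits <- 0; B <- 0
  withr::with_seed(as.integer(seed), {
    for (b in sort(unique(as.integer(schedule)))) {
      draw <- b - B # escalation reuses earlier draws
      U <- A %*% matrix(stats::rnorm(m * draw), m, draw)
      hits <- hits + sum(colSums(U^2) >= S)
      B <- b
      if (hits >= 100) break
    }
  })
  list(stat = S, p = (1 + hits) / (B + 1), n_sims = B, n_snps = m)
}

#' Gene-based scan over all genes
#'
#' Runs [gene_empirical_p()] for every gene in an assignment, taking SNP
#' Z-scores from (meta-analysed) summary statistics and LD from the cohort
#' genotypes. Single-SNP genes take the SNP's own two-sided P directly
#' (the exact 1-df case of the statistic). Per-gene seeds are derived from
#' `(seed, gene_id)`, so results do not depend on gene order.
#'
#' @param stats a `summary_stats`/`meta_result` data.frame with `snp_id`, `z`.
#' @param genotypes LD reference [genotype_matrix()].
#' @param assignment output of [assign_snps()].
#' @param genes annotation data.frame (`gene_id`, `chromosome`, `start`,
#'   `end`) used to carry coordinates into the result.
#' @param schedule,seed passed to [gene_empirical_p()].
#' @return A `gene_results` data.frame: `gene_id`, `chr`, `start`, `end`,
#'   `n_snps`, `stat`, `p`, `n_sims`.
#' @export
gene_based_scan <- function(stats, genotypes, assignment, genes,
                            schedule = c(1e3, 1e4, 1e5), seed = 1L) {
  stats <- as.data.frame(stats)
  rows <- vector("list", length(assignment))
  gmeta <- genes[match(names(assignment), genes$gene_id), ]
  for (i in seq_along(assignment)) {
    gid <- names(assignment)[i]
    ids <- intersect(assignment[[i]], stats$snp_id)
    if (length(ids) == 0) next
    z <- stats$z[match(ids, stats$snp_id)]
    if (length(ids) == 1) {
      S <- z^2
      res <- list(stat = S, p = stats::pchisq(S, 1, lower.tail = FALSE),
                  n_sims = NA_integer_, n_snps = 1L)
    } else {
      ld <- ld_matrix(genotypes, ids)
      res <- gene_empirical_p(z, ld, schedule = schedule,
                              seed = derive_seed(seed, paste0("gene", gid)))
    }
    rows[[i]] <- data.frame(gene_id = gid, chr = gmeta$chromosome[i],
                            start = gmeta$start[i], end = gmeta$end[i],
                            n_snps = res$n_snps, stat = res$stat, p = res$p,
                            n_sims = res$n_sims, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Rank genes by association evidence
#'
#' Orders genes by descending weight `r = -log10(p)`; ties are broken by
#' lexicographic gene id so the ranking is deterministic.
#'
#' @param results a `gene_results` data.frame (needs `gene_id`, `p`).
#' @return A `ranked_genes` data.frame: `gene_id`, `p`, `weight`, `rank`.
#' @export
rank_genes <- function(results) {
  results <- as.data.frame(results)
  if (anyDuplicated(results$gene_id)) stop("duplicate gene ids in results")
  w <- -log10(results$p)
  ord <- order(-w, results$gene_id)
  out <- data.frame(gene_id = results$gene_id[ord], p = results$p[ord],
                    weight = w[ord], stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("ranked_genes", "data.frame")
  out
}
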