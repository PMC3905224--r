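#' Enrichment analysis configuration
#'
#' @param weight_exponent `w` in `{0, 1}`: 1 weights hit increments by the
#'   gene's ranking weight (`-log10 p`), 0 gives the unit-weighted running
#'   sum. Weighted is the usual discovery setting; unit-weighted the usual
#'   replication setting.
#' @param n_perm permutation count for the enrichment null (default 15000).
#' @param n_random_sets random same-size gene sets for empirical validation
#'   (default 1000).
#' @param n_perm_validation per-random-set permutation budget during
#'   validation (default 2000; raise for a full-budget run).
#' @param empirical_criterion fraction of random sets the observed set must
#'   beat on both P and FDR to validate (default 0.95).
#' @param discovery_p_max,discovery_fdr_max discovery criteria: permutation
#'   `P <= 0.05` and/or FDR `q < 0.25`.
#' @param seed integer seed for permutation draws.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(weight_exponent = 1, n_perm = 15000,
                              n_random_sets = 1000, n_perm_validation = 2000,
                              empirical_criterion = 0.95,
                              discovery_p_max = 0.05,
                              discovery_fdr_max = 0.25, seed = 1L) {
  stopifnot(weight_exponent %in% c(0, 1), n_perm >= 1, n_random_sets >= 1,
            empirical_criterion > 0, empirical_criterion < 1)
  structure(list(weight_exponent = weight_exponent, n_perm = as.integer(n_perm),
                 n_random_sets = as.integer(n_random_sets),
                 n_perm_validation = as.integer(n_perm_validation),
                 empirical_criterion = empirical_criterion,
                 discovery_p_max = discovery_p_max,
                 discovery_fdr_max = discovery_fdr_max,
                 seed = as.integer(seed)),
            class = "enrichment_config")
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov-style running sum: walking down the ranking,
#' a gene in the set increments the sum by `r_j^w / sum(hits r^w)` (its
#' ranking weight `r = -log10 p` raised to the exponent, normalized over set
#' members), a gene outside the set decrements it by `1/(N - N_H)`. The
#' enrichment score is the maximum value the running sum attains (one-sided,
#' top-of-list enrichment). Set members absent from the ranking are dropped
#' and counted.
#'
#' @param ranked a `ranked_genes` data.frame from [rank_genes()].
#' @param gene_set character vector of gene ids.
#' @param w weight exponent, 0 or 1.
#' @return A list: `es`, `running` (length-N profile), `n_hits`,
#'   `n_dropped` (set members not in the ranking).
#' @export
#' @examples
#' rk <- data.frame(gene_id = c("a", "b", "c", "d"),
#'                  p = c(1e-3, 1e-2, 0.1, 0.5))
#' enrichment_score(rank_genes(rk), c("a"), w = 0)$es # 1
enrichment_score <- function(ranked, gene_set, w = 1) {
  ranked <- as.data.frame(ranked)
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  n_hits <- sum(hit)
  n_dropped <- length(setdiff(gene_set, ranked$gene_id))
  if (n_hits == 0) stop("gene set is disjoint from the ranking")
  if (n_hits == N) stop("gene set covers the whole ranking")
  wts <- if (w == 0) rep(1, N) else ranked$weight^w
  hit_w <- wts * hit
  tot <- sum(hit_w)
  if (tot <= 0) hit_w[hit] <- 1 / n_hits else hit_w <- hit_w / tot
  step <- ifelse(hit, hit_w, -1 / (N - n_hits))
  running <- cumsum(step)
  list(es = max(running), running = running, n_hits = n_hits,
       n_dropped = n_dropped)
}

# Null enrichment scores for B random same-size gene subsets of the ranking.
# Vectorized: only hit positions matter; for sorted hit positions p_1<...<p_s,
# the running sum at hit i is cumw_i/tot - (p_i - i)/(N - s), and the maximum
# over all N positions is attained at a hit position (the sum only decreases
# elsewhere) or is <= 0.
es_null_sample <- function(weights, set_size, B, w = 1) {
  N <- length(weights)
  s <- set_size
  stopifnot(s >= 1, s < N)
  wts <- if (w == 0) rep(1, N) else weights^w
  P <- vapply(seq_len(B), function(b) sort.int(sample.int(N, s)),
              integer(s))
  P <- matrix(P, nrow = s)
  W <- matrix(wts[P], nrow = s)
  CW <- if (s == 1) W else apply(W, 2, cumsum)
  tot <- CW[s, ]
  deg <- tot <= 0 # all-zero hit weights: fall back to unit increments
  if (any(deg)) {
    CW[, deg] <- matrix(seq_len(s) / s, s, sum(deg))
    tot[deg] <- 1
  }
  M <- CW / rep(tot, each = s) - (P - seq_len(s)) / (N - s)
  # the running sum right before the first hit is negative, so the max of M
  # equals the profile maximum whenever positive; clamp at the pre-first-hit
  # value otherwise (profile max can also occur at position 0 = 0? no: the
  # profile starts after the first step; max(M) handles all hit positions and
  # misses only give smaller values)
  if (s == 1) drop(M) else apply(M, 2, max)
}

#' Permutation P-value for an observed enrichment score
#'
#' Draws `n_perm` random gene subsets of the candidate set's size from the
#' ranking (gene-label permutation) and scores each; the P-value is the
#' add-one-corrected fraction of permuted scores at least as large as the
#' observed one.
#'
#' @param ranked a `ranked_genes` data.frame.
#' @param set_size size of the permuted sets (the candidate's in-ranking size).
#' @param observed_es observed enrichment score.
#' @param config an [enrichment_config()].
#' @return A list: `p_perm`, `null_es` (the permuted score sample).
#' @export
permutation_p <- function(ranked, set_size, observed_es, config) {
  ranked <- as.data.frame(ranked)
  stopifnot(set_size >= 1, set_size < nrow(ranked))
  null_es <- withr::with_seed(config$seed,
    es_null_sample(ranked$weight, set_size, config$n_perm,
                   config$weight_exponent))
  p <- (1 + sum(null_es >= observed_es)) / (config$n_perm + 1)
  list(p_perm = p, null_es = null_es)
}

#' GSEA-style FDR q-values across gene sets
#'
#' Each set's score is normalized by the mean of the positive part of its
#' own permutation null (`NES = ES / mean(null ES > 0)`); permuted scores
#' are normalized the same way and pooled. A set's q is the pooled-null tail
#' fraction at its NES divided by the observed tail fraction, clipped to
#' `[0, 1]` and monotonized so q never decreases as NES decreases. With a
#' single set the estimator collapses to its permutation P.
#'
#' @param es_list numeric vector of observed scores (named by set).
#' @param null_list list of permutation null score vectors, parallel to
#'   `es_list`.
#' @param p_perm numeric vector of permutation P-values (used for the
#'   single-set collapse).
#' @return A list: `nes` and `q`, named like `es_list`.
#' @export
fdr_q <- function(es_list, null_list, p_perm) {
  k <- length(es_list)
  stopifnot(length(null_list) == k, length(p_perm) == k)
  if (k == 1) {
    mu <- mean(null_list[[1]][null_list[[1]] > 0])
    return(list(nes = es_list / mu, q = unname(p_perm)))
  }
  mu <- vapply(null_list, function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0) stop("no positive null enrichment scores for a set")
    mean(pos)
  }, 0)
  nes <- es_list / mu
  null_nes <- unlist(lapply(seq_len(k), function(i) null_list[[i]] / mu[i]))
  q <- vapply(seq_len(k), function(i) {
    num <- mean(null_nes >= nes[i])
    den <- mean(nes >= nes[i])
    min(1, num / den)
  }, 0)
  # step-up monotonization: a set's q is the smallest raw q among itself and
  # every less-enriched set, so q never decreases as NES decreases
  ord <- order(-nes)
  q[ord] <- rev(cummin(rev(q[ord])))
  list(nes = nes, q = q)
}

#' Competitive enrichment analysis of gene sets against a ranking
#'
#' Computes, for each candidate set, the running-sum enrichment score, its
#' permutation P (add-one corrected over `n_perm` random same-size subsets),
#' the normalized score and GSEA-style FDR q across the sets, and the
#' discovery flag (`P <= discovery_p_max` and/or `q < discovery_fdr_max`).
#'
#' @param ranked a `ranked_genes` data.frame.
#' @param collection a [gene_set_collection()] (or named list of id vectors).
#' @param config an [enrichment_config()].
#' @return An `enrichment_results` data.frame: `set`, `n_genes`,
#'   `n_dropped`, `es`, `nes`, `p_perm`, `fdr_q`, `discovery`; the
#'   permutation nulls are attached as attribute `null_es` for downstream
#'   validation.
#' @export
gsea <- function(ranked, collection, config = enrichment_config()) {
  sets <- if (inherits(collection, "gene_set_collection")) {
    collection$sets
  } else {
    collection
  }
  usable <- names(sets)[vapply(sets, function(s) {
    n <- sum(ranked$gene_id %in% s)
    n >= 1 && n < nrow(ranked)
  }, TRUE)]
  if (length(usable) == 0) stop("no testable gene set")
  es <- numeric(0); nulls <- list(); pp <- numeric(0)
  n_in <- integer(0); n_drop <- integer(0)
  for (nm in usable) {
    sc <- enrichment_score(ranked, sets[[nm]], config$weight_exponent)
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, paste0("perm_", nm))
    pr <- permutation_p(ranked, sc$n_hits, sc$es, cfg_i)
    es[nm] <- sc$es
    nulls[[nm]] <- pr$null_es
    pp[nm] <- pr$p_perm
    n_in[nm] <- sc$n_hits
    n_drop[nm] <- sc$n_dropped
  }
  fq <- fdr_q(es, nulls, pp)
  out <- data.frame(
    set = usable, n_genes = n_in, n_dropped = n_drop, es = unname(es),
    nes = unname(fq$nes), p_perm = unname(pp), fdr_q = unname(fq$q),
    discovery = unname(pp <= config$discovery_p_max |
                         fq$q < config$discovery_fdr_max),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "null_es") <- nulls
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Empirical validation against random gene sets
#'
#' Draws `n_random_sets` random gene sets of the candidate's in-ranking
#' size, scores each with a reduced permutation budget
#' (`n_perm_validation`), computes each random set's P and (batch) FDR q,
#' and reports the fractions of random sets whose P and q exceed the
#' observed ones. The set validates when both fractions reach
#' `empirical_criterion`.
#'
#' @param ranked a `ranked_genes` data.frame.
#' @param gene_set candidate gene ids.
#' @param observed_p,observed_q the candidate's permutation P and FDR q.
#' @param config an [enrichment_config()].
#' @return A list: `fraction_exceeding_p`, `fraction_exceeding_fdr`,
#'   `validated`, and the random-set `random_p`, `random_q` samples.
#' @export
empirical_validation <- function(ranked, gene_set, observed_p, observed_q,
                                 config = enrichment_config()) {
  ranked <- as.data.frame(ranked)
  N <- nrow(ranked)
  size <- sum(ranked$gene_id %in% gene_set)
  stopifnot(size >= 1, size < N)
  R <- config$n_random_sets
  B <- config$n_perm_validation
  es_r <- numeric(R); nulls <- vector("list", R)
  withr::with_seed(derive_seed(config$seed, "validation"), {
    for (r in seq_len(R)) {
      idx <- sample.int(N, size)
      sc <- enrichment_score(ranked, ranked$gene_id[idx],
                             config$weight_exponent)
      nulls[[r]] <- es_null_sample(ranked$weight, size, B,
                                   config$weight_exponent)
      es_r[r] <- sc$es
    }
  })
  p_r <- vapply(seq_len(R), function(r) {
    (1 + sum(nulls[[r]] >= es_r[r])) / (B + 1)
  }, 0)
  q_r <- fdr_q(es_r, nulls, p_r)$q
  frac_p <- mean(p_r > observed_p)
  frac_q <- mean(q_r > observed_q)
  list(fraction_exceeding_p = frac_p, fraction_exceeding_fdr = frac_q,
       validated = frac_p >= config$empirical_criterion &&
         frac_q >= config$empirical_criterion,
       random_p = p_r, random_q = q_r)
}

#' Leave-one-out sensitivity of an enrichment result
#'
#' Removes the set member with the largest ranking weight (the most
#' significant gene), recomputes the enrichment score and permutation P,
#' and records the removed gene: a set whose signal survives removal is not
#' driven by a single gene.
#'
#' @param ranked a `ranked_genes` data.frame.
#' @param gene_set candidate gene ids (at least 2 in the ranking).
#' @param config an [enrichment_config()].
#' @return A list: `removed_gene`, `es`, `p_perm`, `n_hits`.
#' @export
leave_one_out <- function(ranked, gene_set, config = enrichment_config()) {
  ranked <- as.data.frame(ranked)
  members <- ranked[ranked$gene_id %in% gene_set, ]
  if (nrow(members) < 2) {
    stop("leave-one-out needs at least 2 set members in the ranking")
  }
  top <- members$gene_id[which.max(members$weight)]
  reduced <- setdiff(gene_set, top)
  sc <- enrichment_score(ranked, reduced, config$weight_exponent)
  cfg <- config
  cfg$seed <- derive_seed(config$seed, paste0("loo_", top))
  pr <- permutation_p(ranked, sc$n_hits, sc$es, cfg)
  list(removed_gene = top, es = sc$es, p_perm = pr$p_perm,
       n_hits = sc$n_hits)
}
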