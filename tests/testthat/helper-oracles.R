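# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (enumeration, direct formulas) and never
# call the implementation paths they check.

# Brute-force running-sum enrichment score: literal walk down the ranking.
oracle_enrichment_score <- function(weights, hit, w) {
  N <- length(weights)
  nh <- sum(hit)
  wts <- if (w == 0) rep(1, N) else weights^w
  tot <- sum(wts[hit])
  run <- numeric(N)
  acc <- 0
  for (j in seq_len(N)) {
    acc <- if (hit[j]) {
      acc + (if (tot > 0) wts[j] / tot else 1 / nh)
    } else {
      acc - 1 / (N - nh)
    }
    run[j] <- acc
  }
  list(es = max(run), running = run)
}

# Direct-formula exact HWE P: enumerate every heterozygote count with the
# conditional probability written out in factorials (no recurrences, no
# log-space tricks beyond lfactorial).
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  prob <- sapply(hets, function(h) {
    exp(lfactorial(n) - lfactorial((nm - h) / 2) - lfactorial(h) -
          lfactorial(n - (nm + h) / 2) + h * log(2) +
          lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n))
  })
  p_obs <- prob[hets == n_Aa]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Small deterministic ranking fixture: N genes named g01.., given p-values.
make_ranking <- function(p, ids = sprintf("g%02d", seq_along(p))) {
  rank_genes(data.frame(gene_id = ids, p = p))
}

# Tiny simulated study shared by several test files (kept small: n=400,
# 60 genes); built once per test run.
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 400, n_genes = 60,
                        snps_per_gene = c(2, 4), causal_set_size = 10,
                        h2_set = 0.3, ld_rho = 0.6, seed = 101)
      ann <- make_gene_annotation(cfg)
      gt <- simulate_genotypes(ann, cfg, 1)
      sets <- make_gene_sets(ann, cfg)
      ph <- simulate_phenotypes(gt, ann, sets$sets$causal, cfg, 1)
      cache <<- list(cfg = cfg, ann = ann, gt = gt, sets = sets, ph = ph)
    }
    cache
  }
})
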