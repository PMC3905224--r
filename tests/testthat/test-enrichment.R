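test_that("enrichment score reproduces hand-computed running sums", {
  # N=4, unit weights, set = {rank 1}: running (1, 2/3, 1/3, 0), ES = 1
  rk <- make_ranking(c(1e-3, 1e-2, 0.1, 0.5))
  sc <- enrichment_score(rk, rk$gene_id[1], w = 0)
  expect_equal(sc$running, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(sc$es, 1.0, tolerance = 1e-12)

  # set = {rank 2}: ES = 2/3
  sc2 <- enrichment_score(rk, rk$gene_id[2], w = 0)
  expect_equal(sc2$es, 2 / 3, tolerance = 1e-12)

  # weighted: weights (3,2,1,0.5), set = {ranks 1,2}:
  # running (3/5, 1, 1/2, 0), ES = 1
  rkw <- make_ranking(10^-c(3, 2, 1, 0.5))
  sc3 <- enrichment_score(rkw, rkw$gene_id[1:2], w = 1)
  expect_equal(sc3$running, c(3 / 5, 1, 1 / 2, 0), tolerance = 1e-10)
  expect_equal(sc3$es, 1.0, tolerance = 1e-10)

  # set members missing from the ranking are dropped and counted
  sc4 <- enrichment_score(rk, c(rk$gene_id[1], "absent1", "absent2"), w = 0)
  expect_identical(sc4$n_hits, 1L)
  expect_identical(sc4$n_dropped, 2L)

  expect_error(enrichment_score(rk, c("nope"), w = 0), "disjoint")
  expect_error(enrichment_score(rk, rk$gene_id, w = 0), "whole ranking")
})

test_that("enrichment score matches the brute-force oracle on every subset
           of small rankings", {
  set.seed(20)
  for (N in c(3, 5, 8)) {
    p <- sort(runif(N, 1e-6, 1))
    rk <- make_ranking(p)
    for (w in c(0, 1)) {
      for (mask in 1:(2^N - 2)) {
        hit <- as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))
        sc <- enrichment_score(rk, rk$gene_id[hit], w = w)
        orc <- oracle_enrichment_score(rk$weight, hit, w)
        expect_equal(sc$running, orc$running, tolerance = 1e-12)
        expect_equal(sc$es, orc$es, tolerance = 1e-12)
      }
    }
  }
})

test_that("running sum conserves increments and obeys weight invariances", {
  set.seed(21)
  rk <- make_ranking(runif(60, 1e-8, 1))
  set <- sample(rk$gene_id, 12)
  sc1 <- enrichment_score(rk, set, w = 1)
  expect_lt(abs(sc1$running[60]), 1e-10) # ends exactly at 0

  # w=1: invariant under positive rescaling of all weights
  rk_scaled <- rk
  rk_scaled$weight <- rk$weight * 7.3
  expect_equal(enrichment_score(rk_scaled, set, w = 1)$es, sc1$es,
               tolerance = 1e-12)
  # w=0: invariant under any weight change
  rk_shuffled <- rk
  rk_shuffled$weight <- rev(rk$weight)
  expect_equal(enrichment_score(rk_shuffled, set, w = 0)$es,
               enrichment_score(rk, set, w = 0)$es, tolerance = 1e-12)
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(22)
  rk <- make_ranking(runif(100, 1e-7, 1))
  stats <- setNames(rk$weight, rk$gene_id)
  for (size in c(5, 20)) {
    set <- sample(rk$gene_id, size)
    es <- enrichment_score(rk, set, w = 1)$es
    es_fgsea <- fgsea::calcGseaStat(stats, which(rk$gene_id %in% set),
                                    gseaParam = 1, scoreType = "pos")
    expect_equal(es, es_fgsea, tolerance = 1e-10)
  }
})

test_that("permutation p follows the add-one counting rule bit-for-bit", {
  set.seed(23)
  rk <- make_ranking(runif(50, 1e-6, 1))
  cfg <- enrichment_config(n_perm = 200, seed = 9)
  sc <- enrichment_score(rk, rk$gene_id[c(2, 5, 11)], w = 1)
  pr1 <- permutation_p(rk, 3, sc$es, cfg)
  pr2 <- permutation_p(rk, 3, sc$es, cfg)
  expect_identical(pr1, pr2) # reproducible at fixed seed
  expect_equal(pr1$p_perm,
               (1 + sum(pr1$null_es >= sc$es)) / (cfg$n_perm + 1),
               tolerance = 1e-15)
  expect_length(pr1$null_es, 200)
  # observed larger than every permuted score: p hits the add-one bound
  pr_top <- permutation_p(rk, 3, max(pr1$null_es) + 1, cfg)
  expect_equal(pr_top$p_perm, 1 / 201, tolerance = 1e-15)

  # null permutation scores match a brute-force per-set rescoring
  ones <- withr::with_seed(777, {
    idx <- replicate(50, sort(sample.int(50, 3)), simplify = FALSE)
    vapply(idx, function(ix) {
      enrichment_score(rk, rk$gene_id[ix], w = 1)$es
    }, 0)
  })
  null_big <- permutation_p(rk, 3, 0.5, enrichment_config(n_perm = 2000,
                                                          seed = 1))$null_es
  expect_gt(suppressWarnings(ks.test(ones, null_big))$p.value, 0.01)
})

test_that("permutation p of a null-drawn observed score is uniform", {
  set.seed(24)
  rk <- make_ranking(runif(80, 1e-6, 1))
  cfg <- enrichment_config(n_perm = 199, seed = 31)
  pvals <- sapply(1:200, function(r) {
    idx <- sample.int(80, 8)
    sc <- enrichment_score(rk, rk$gene_id[idx], w = 1)
    cfg$seed <- r
    permutation_p(rk, 8, sc$es, cfg)$p_perm
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("fdr_q collapses to p for one set, is symmetric, and matches a
           brute-force ratio estimator", {
  # single set: q = permutation p
  expect_equal(fdr_q(c(s1 = 0.8), list(rnorm(100)^2 / 10), 0.031)$q, 0.031)

  # two identical sets get identical q
  null <- abs(rnorm(500))
  fq2 <- fdr_q(c(a = 0.7, b = 0.7), list(null, null), c(0.1, 0.1))
  expect_equal(fq2$q[1], fq2$q[2], tolerance = 1e-12)

  # five synthetic sets against an independent implementation of the same
  # NES-ratio estimator
  set.seed(25)
  es <- c(0.9, 0.7, 0.5, 0.45, 0.2)
  nulls <- lapply(1:5, function(i) abs(rnorm(400, sd = 0.25)))
  fq <- fdr_q(es, nulls, rep(0.5, 5))
  mu <- sapply(nulls, function(x) mean(x[x > 0]))
  nes <- es / mu
  pooled <- unlist(lapply(1:5, function(i) nulls[[i]] / mu[i]))
  raw <- sapply(1:5, function(i) {
    min(1, mean(pooled >= nes[i]) / mean(nes >= nes[i]))
  })
  # step-up adjustment, written longhand: each set takes the smallest raw q
  # among itself and every set with lower or equal NES
  adj <- sapply(1:5, function(i) min(raw[nes <= nes[i]]))
  expect_equal(fq$nes, nes, tolerance = 1e-12)
  expect_equal(fq$q, adj, tolerance = 1e-12)
})

test_that("empirical validation fractions behave at the boundaries and
           calibrate near 1 - criterion under the null", {
  set.seed(26)
  rk <- make_ranking(runif(60, 1e-6, 1))
  cfg <- enrichment_config(n_random_sets = 100, n_perm_validation = 99,
                           empirical_criterion = 0.95, seed = 5)
  # observed p smaller than anything attainable by the random sets
  v <- empirical_validation(rk, rk$gene_id[1:6], observed_p = 1e-9,
                            observed_q = 1e-9, config = cfg)
  expect_equal(v$fraction_exceeding_p, 1.0)
  expect_true(v$validated)
  # observed p larger than all: fraction 0, not validated
  v0 <- empirical_validation(rk, rk$gene_id[1:6], observed_p = 1,
                             observed_q = 1, config = cfg)
  expect_equal(v0$fraction_exceeding_p, 0)
  expect_false(v0$validated)

  # calibration: a random observed set validates with probability
  # ~ 1 - criterion; check the rejection rate is far below 50%
  cfg_small <- enrichment_config(n_random_sets = 60, n_perm_validation = 99,
                                 empirical_criterion = 0.95, seed = 5)
  hits <- sapply(1:30, function(r) {
    idx <- sample.int(60, 6)
    sc <- enrichment_score(rk, rk$gene_id[idx], w = 1)
    ccc <- cfg_small
    ccc$seed <- 1000 + r
    pr <- permutation_p(rk, 6, sc$es, ccc)
    empirical_validation(rk, rk$gene_id[idx], observed_p = pr$p_perm,
                         observed_q = pr$p_perm, config = ccc)$validated
  })
  expect_lte(mean(hits), 0.2) # ~0.05 expected; binomial slack at 30 reps
})

test_that("leave-one-out removes the top-ranked member and reveals whether
           one gene drives the signal", {
  set.seed(27)
  # two mid-ranked members: result equals the single lower member
  rk <- make_ranking(sort(runif(40, 1e-4, 1)))
  cfg <- enrichment_config(n_perm = 199, seed = 3)
  two <- rk$gene_id[c(10, 25)]
  loo <- leave_one_out(rk, two, cfg)
  expect_identical(loo$removed_gene, rk$gene_id[10])
  expect_equal(loo$es, enrichment_score(rk, rk$gene_id[25], w = 1)$es,
               tolerance = 1e-12)

  # enrichment driven by one extreme gene collapses after removal
  p_one <- c(1e-10, sort(runif(39, 0.3, 1)))
  rk1 <- make_ranking(p_one)
  driver_set <- rk1$gene_id[c(1, 20, 30, 35)]
  before <- gsea(rk1, list(s = driver_set), cfg)
  loo1 <- leave_one_out(rk1, driver_set, cfg)
  expect_identical(loo1$removed_gene, rk1$gene_id[1])
  expect_lt(before$p_perm, 0.05)
  expect_gt(loo1$p_perm, 0.05)

  # enrichment spread over many genes survives removal
  p_spread <- c(sort(runif(20, 1e-6, 1e-3)), sort(runif(80, 0.05, 1)))
  rk2 <- make_ranking(p_spread)
  spread_set <- rk2$gene_id[1:20]
  loo2 <- leave_one_out(rk2, spread_set, cfg)
  expect_lt(loo2$p_perm, 0.05)

  expect_error(leave_one_out(rk, rk$gene_id[1], cfg), "at least 2")
})

test_that("gsea table carries discovery flags and set accounting", {
  set.seed(28)
  rk <- make_ranking(c(sort(runif(10, 1e-6, 1e-3)), runif(90, 0.1, 1)))
  sets <- gene_set_collection(list(
    strong = rk$gene_id[1:10],
    weak = sample(rk$gene_id[21:100], 10),
    everything = rk$gene_id
  ))
  res <- gsea(rk, sets, enrichment_config(n_perm = 499, seed = 11))
  expect_identical(res$set, c("strong", "weak")) # full-ranking set untestable
  expect_true(res$discovery[res$set == "strong"])
  expect_gte(min(res$p_perm), 1 / 500)
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  expect_true(all(res$es >= -1 & res$es <= 1))
})
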