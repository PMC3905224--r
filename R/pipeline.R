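#' Full pipeline configuration
#'
#' Bundles the per-stage settings of the simulate -> phenotype -> associate
#' -> meta-analyse -> gene-test -> enrich -> validate -> combine chain with
#' the field-standard defaults: a 50 kb gene window, 15 000 enrichment
#' permutations, 1000 random validation sets with a 0.95 criterion, and the
#' usual array QC thresholds.
#'
#' @param sim a [sim_config()]; its `seed` is the run's master seed.
#' @param qc a [qc_thresholds()].
#' @param window_kb SNP-to-gene assignment window (kb each side).
#' @param gene_schedule Monte-Carlo schedule for [gene_empirical_p()].
#' @param enrich an [enrichment_config()]; its seed is re-derived from the
#'   master seed.
#' @param residualize_after if `TRUE` (default) factor scores are extracted
#'   first and then residualized on age and sex; if `FALSE` each test is
#'   residualized before extraction.
#' @param validate if `TRUE`, sets meeting the discovery criteria are
#'   empirically validated against random gene sets.
#' @param evidence_m number of tests for the Bonferroni correction of
#'   enrichment P-values (default: number of sets tested).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_thresholds(),
                            window_kb = 50,
                            gene_schedule = c(1e3, 1e4, 1e5),
                            enrich = enrichment_config(),
                            residualize_after = TRUE,
                            validate = FALSE,
                            evidence_m = NULL) {
  structure(list(sim = sim, qc = qc, window_kb = window_kb,
                 gene_schedule = gene_schedule, enrich = enrich,
                 residualize_after = residualize_after,
                 validate = isTRUE(validate), evidence_m = evidence_m),
            class = "pipeline_config")
}

#' Build a phenotype score from a battery (both residualisation orders)
#'
#' @param phenotypes list with `battery`, `age`, `sex` (and `sample_ids`).
#' @param residualize_after extract first and residualize the factor score
#'   (`TRUE`), or residualize every test column first (`FALSE`).
#' @return Named numeric vector of standardized scores.
#' @export
phenotype_scores <- function(phenotypes, residualize_after = TRUE) {
  b <- phenotypes$battery
  rownames(b) <- phenotypes$sample_ids
  if (residualize_after) {
    residualize_age_sex(gf_scores(b), phenotypes$age, phenotypes$sex)
  } else {
    rb <- apply(b, 2, function(col) {
      residualize_age_sex(col, phenotypes$age, phenotypes$sex)
    })
    rownames(rb) <- phenotypes$sample_ids
    gf_scores(rb)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the processing stages top to bottom: simulate cohorts,
#' construct phenotype scores, per-cohort QC + association, inverse-variance
#' meta-analysis, LD-aware gene-based test on the meta-analysis (LD
#' reference: the largest cohort's post-QC genotypes), competitive gene-set
#' enrichment, optional empirical validation of discovery sets, and the
#' evidence stage (Bonferroni-corrected enrichment P per set). With an
#' `out_dir`, every stage's output is written before the next starts
#' (dosage TSV, phenotype TSV, summary TSV, results TSVs, GMT, BED and a
#' JSON manifest) and a re-run with `resume = TRUE` picks up from existing
#' stage files, reproducing the remaining outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for stage outputs (`NULL` = in memory only).
#' @param resume reuse existing stage files in `out_dir`.
#' @param quiet suppress per-stage messages.
#' @return A list of class `pipeline_run`: `manifest` (config snapshot,
#'   master seed, derived seeds, per-stage counts, file checksums) and the
#'   stage outputs (`annotation`, `gene_sets`, `scores`, `assoc`, `meta`,
#'   `gene_results`, `ranked`, `enrichment`, `validation`, `evidence`).
#' @export
run_pipeline <- function(config, out_dir = NULL, resume = TRUE,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  seed <- sim$seed
  io <- !is.null(out_dir)
  if (io && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pathof <- function(f) file.path(out_dir, f)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(config = unclass_deep(config), master_seed = seed,
                   seeds = list(), stages = list(), files = character())
  st <- list()

  # -- simulate ---------------------------------------------------------
  have <- io && resume && file.exists(pathof("annotation.bed")) &&
    file.exists(pathof("gene_sets.gmt")) &&
    all(file.exists(pathof(sprintf("genotypes_cohort%d.tsv",
                                   seq_len(sim$n_cohorts)))))
  if (have) {
    say("simulate: resuming from files")
    st$annotation <- list(genes = read_gene_bed(pathof("annotation.bed")),
                          snps = NULL)
    st$gene_sets <- read_gmt(pathof("gene_sets.gmt"))
    st$genotypes <- lapply(seq_len(sim$n_cohorts), function(k) {
      read_dosage_tsv(pathof(sprintf("genotypes_cohort%d.tsv", k)))
    })
    st$annotation$snps <- st$genotypes[[1]]$snps
    st$phenotypes <- lapply(seq_len(sim$n_cohorts), function(k) {
      read_phenotype_tsv(pathof(sprintf("phenotypes_cohort%d.tsv", k)))
    })
  } else {
    st$annotation <- make_gene_annotation(sim)
    st$gene_sets <- make_gene_sets(st$annotation, sim)
    st$genotypes <- lapply(seq_len(sim$n_cohorts), function(k) {
      simulate_genotypes(st$annotation, sim, k)
    })
    st$phenotypes <- lapply(seq_len(sim$n_cohorts), function(k) {
      simulate_phenotypes(st$genotypes[[k]], st$annotation,
                          st$gene_sets$sets$causal, sim, k)
    })
    if (io) {
      write_gene_bed(st$annotation$genes, pathof("annotation.bed"))
      write_gmt(st$gene_sets, pathof("gene_sets.gmt"))
      for (k in seq_len(sim$n_cohorts)) {
        write_dosage_tsv(st$genotypes[[k]],
                         pathof(sprintf("genotypes_cohort%d.tsv", k)))
        write_phenotype_tsv(st$phenotypes[[k]],
                            pathof(sprintf("phenotypes_cohort%d.tsv", k)))
      }
    }
  }
  manifest$stages$simulate <- list(
    n_genes = nrow(st$annotation$genes),
    n_snps = nrow(st$annotation$snps),
    n_samples = vapply(st$genotypes, function(g) length(g$sample_ids), 0L)
  )

  # -- phenotype scores -------------------------------------------------
  st$scores <- lapply(st$phenotypes, phenotype_scores,
                      residualize_after = config$residualize_after)
  if (io) {
    for (k in seq_len(sim$n_cohorts)) {
      write_scores_tsv(st$scores[[k]], pathof(sprintf("scores_cohort%d.tsv", k)))
    }
  }

  # -- per-cohort QC + association --------------------------------------
  assoc_files <- pathof(sprintf("assoc_cohort%d.tsv", seq_len(sim$n_cohorts)))
  if (io && resume && all(file.exists(assoc_files))) {
    say("assoc: resuming from files")
    st$assoc <- lapply(assoc_files, read_summary_tsv)
    st$post_qc <- lapply(seq_len(sim$n_cohorts), function(k) {
      keep <- st$genotypes[[k]]$snps$snp_id %in% st$assoc[[k]]$snp_id
      genotype_matrix(st$genotypes[[k]]$dosage[, keep, drop = FALSE],
                      st$genotypes[[k]]$snps[keep, , drop = FALSE],
                      st$genotypes[[k]]$sample_ids)
    })
  } else {
    st$post_qc <- vector("list", sim$n_cohorts)
    st$assoc <- vector("list", sim$n_cohorts)
    for (k in seq_len(sim$n_cohorts)) {
      q <- qc_filter(st$genotypes[[k]], config$qc)
      say("assoc cohort ", k, ": ", nrow(q$report), " SNP(s) removed by QC")
      st$post_qc[[k]] <- q$genotypes
      st$assoc[[k]] <- snp_association(q$genotypes, st$scores[[k]])
      if (io) write_summary_tsv(st$assoc[[k]], assoc_files[k])
    }
  }
  manifest$stages$assoc <- list(
    n_snps_post_qc = vapply(st$assoc, nrow, 0L)
  )

  # -- meta-analysis ----------------------------------------------------
  if (io && resume && file.exists(pathof("meta.tsv"))) {
    st$meta <- read_summary_tsv(pathof("meta.tsv"))
  } else {
    st$meta <- ivw_meta(st$assoc)
    if (io) write_summary_tsv(st$meta, pathof("meta.tsv"))
  }
  manifest$stages$meta <- list(n_snps = nrow(st$meta))

  # -- gene-based test --------------------------------------------------
  ld_ref <- st$post_qc[[which.max(vapply(st$post_qc, function(g) {
    length(g$sample_ids)
  }, 0L))]]
  if (io && resume && file.exists(pathof("gene_results.tsv"))) {
    st$gene_results <- read_results_tsv(pathof("gene_results.tsv"),
                                        "gene_results")
  } else {
    usable <- st$meta[st$meta$snp_id %in% ld_ref$snps$snp_id, ]
    assignment <- assign_snps(
      data.frame(snp_id = usable$snp_id, chromosome = usable$chr,
                 position = usable$pos),
      st$annotation$genes, config$window_kb
    )
    st$gene_results <- gene_based_scan(usable, ld_ref, assignment,
                                       st$annotation$genes,
                                       schedule = config$gene_schedule,
                                       seed = derive_seed(seed, "gene_test"))
    if (io) write_results_tsv(st$gene_results, pathof("gene_results.tsv"))
  }
  st$ranked <- rank_genes(st$gene_results)
  dropped_genes <- nrow(st$annotation$genes) - nrow(st$gene_results)
  say("gene test: ", nrow(st$gene_results), " genes scored, ",
      dropped_genes, " without SNPs dropped")
  manifest$stages$gene_test <- list(n_genes_scored = nrow(st$gene_results),
                                    n_genes_dropped = dropped_genes)

  # -- enrichment -------------------------------------------------------
  ecfg <- config$enrich
  ecfg$seed <- derive_seed(seed, "enrichment")
  manifest$seeds$enrichment <- ecfg$seed
  st$enrichment <- gsea(st$ranked, st$gene_sets, ecfg)
  if (io) write_results_tsv(st$enrichment, pathof("enrichment.tsv"))
  manifest$stages$enrichment <- list(n_sets = nrow(st$enrichment))

  # -- empirical validation ---------------------------------------------
  if (config$validate) {
    st$validation <- list()
    for (i in which(st$enrichment$discovery)) {
      nm <- st$enrichment$set[i]
      vcfg <- ecfg
      vcfg$seed <- derive_seed(seed, paste0("validate_", nm))
      st$validation[[nm]] <- empirical_validation(
        st$ranked, st$gene_sets$sets[[nm]],
        observed_p = st$enrichment$p_perm[i],
        observed_q = st$enrichment$fdr_q[i], config = vcfg
      )[c("fraction_exceeding_p", "fraction_exceeding_fdr", "validated")]
    }
    if (io) {
      jsonlite::write_json(st$validation, pathof("validation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  # -- evidence ---------------------------------------------------------
  m <- config$evidence_m %||% nrow(st$enrichment)
  st$evidence <- data.frame(
    set = st$enrichment$set,
    p_perm = st$enrichment$p_perm,
    p_bonferroni = bonferroni(st$enrichment$p_perm, m),
    m_tests = m,
    stringsAsFactors = FALSE
  )
  if (io) write_results_tsv(st$evidence, pathof("evidence.tsv"))

  if (io) {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$files <- as.list(tools::md5sum(files))
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, pathof("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(c(list(manifest = manifest),
              st[c("annotation", "gene_sets", "scores", "assoc", "meta",
                   "gene_results", "ranked", "enrichment", "validation",
                   "evidence")]),
            class = "pipeline_run")
}

# Strip S3 classes recursively so a config snapshot serializes cleanly.
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Combine per-cohort enrichment evidence across cohorts
#'
#' Convenience wrapper over [stouffer_weighted()] for a table of cohort
#' results, applying an optional Bonferroni correction to the discovery
#' cohort before combination.
#'
#' @param cohorts data.frame with columns `cohort`, `p`, `n`; optionally
#'   `m` (per-cohort Bonferroni test counts, default 1 = no correction).
#' @return A list: `p_combined`, `z_combined`, `cohorts` table with the
#'   corrected P and Z contributions.
#' @export
combine_cohort_evidence <- function(cohorts) {
  stopifnot(all(c("cohort", "p", "n") %in% names(cohorts)))
  m <- if ("m" %in% names(cohorts)) cohorts$m else rep(1L, nrow(cohorts))
  p_corr <- mapply(bonferroni, cohorts$p, m)
  res <- stouffer_weighted(p_corr, cohorts$n)
  res$cohorts <- cbind(cohort = cohorts$cohort, res$cohorts)
  res
}
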