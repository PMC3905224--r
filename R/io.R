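#' @name pipeline_io
#' @title File formats of the pipeline
#' @description Readers and writers for every interchange format the
#' pipeline touches: genotype dosages (TSV, VCF with a `DS` FORMAT field,
#' PLINK bed/bim/fam hard calls), gene annotation (BED, 0-based half-open on
#' disk, 1-based inclusive in memory), gene sets (GMT), phenotype/covariate
#' tables (TSV), summary statistics, gene results and enrichment results
#' (TSV with fixed headers; readers tolerate extra columns). Every pair
#' round-trips: `read(write(x))` reproduces the internal representation.
NULL

# fwrite with bit-exact doubles: %.17g survives the text round trip,
# so resumed runs reproduce in-memory results identically
fwrite_exact <- function(tab, path) {
  tab <- data.table::as.data.table(tab)
  for (j in names(tab)) {
    if (is.double(tab[[j]])) {
      v <- sprintf("%.17g", tab[[j]])
      v[is.na(tab[[j]])] <- NA
      data.table::set(tab, j = j, value = v)
    }
  }
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param genotypes a [genotype_matrix()].
#' @param path,prefix output file path (or PLINK fileset prefix).
#' @export
write_dosage_tsv <- function(genotypes, path) {
  D <- t(genotypes$dosage)
  tab <- data.table::data.table(
    snp_id = genotypes$snps$snp_id,
    chr = genotypes$snps$chromosome,
    pos = genotypes$snps$position,
    ref = genotypes$snps$ref_allele,
    alt = genotypes$snps$alt_allele
  )
  tab <- cbind(tab, data.table::as.data.table(D))
  data.table::setnames(tab, c("snp_id", "chr", "pos", "ref", "alt",
                              genotypes$sample_ids))
  fwrite_exact(tab, path)
}

#' @rdname pipeline_io
#' @export
read_dosage_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  meta_cols <- c("snp_id", "chr", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    stop("malformed dosage TSV: expected columns ",
         paste(meta_cols, collapse = ", "))
  }
  sample_ids <- setdiff(names(tab), meta_cols)
  D <- t(as.matrix(tab[, sample_ids, with = FALSE]))
  snps <- data.frame(snp_id = tab$snp_id, chromosome = tab$chr,
                     position = tab$pos, ref_allele = tab$ref,
                     alt_allele = tab$alt, stringsAsFactors = FALSE)
  genotype_matrix(D, snps, sample_ids)
}

#' @rdname pipeline_io
#' @export
write_vcf_dosage <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  ), con)
  ds <- t(genotypes$dosage)
  body <- vapply(seq_len(nrow(ds)), function(i) {
    vals <- ifelse(is.na(ds[i, ]), ".", format(ds[i, ], trim = TRUE,
                                               scientific = FALSE))
    paste(c(genotypes$snps$chromosome[i], genotypes$snps$position[i],
            genotypes$snps$snp_id[i], genotypes$snps$ref_allele[i],
            genotypes$snps$alt_allele[i], ".", "PASS", ".", "DS", vals),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  snps <- data.frame(
    snp_id = unname(fix[, "ID"]),
    chromosome = suppressWarnings(as.integer(fix[, "CHROM"])),
    position = as.integer(fix[, "POS"]),
    ref_allele = unname(fix[, "REF"]),
    alt_allele = unname(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  if (anyNA(snps$chromosome)) snps$chromosome <- unname(fix[, "CHROM"])
  genotype_matrix(t(ds), snps, colnames(ds))
}

#' @rdname pipeline_io
#' @details PLINK bed files store hard calls; writing rounds dosages to the
#' nearest genotype. A1 in the bim file is the alternate (dosage-counted)
#' allele, A2 the reference.
#' @export
write_plink <- function(genotypes, prefix) {
  D <- round(genotypes$dosage)
  n <- nrow(D); m <- ncol(D)
  fam <- data.frame(fid = genotypes$sample_ids, iid = genotypes$sample_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = genotypes$snps$chromosome,
                    snp_id = genotypes$snps$snp_id, cm = 0,
                    pos = genotypes$snps$position,
                    a1 = genotypes$snps$alt_allele,
                    a2 = genotypes$snps$ref_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # SNP-major 2-bit codes: 00=hom A1 (dosage 2), 10=het, 11=hom A2, 01=missing
  code <- matrix(3L, n, m)
  code[D == 2] <- 0L
  code[D == 1] <- 2L
  code[is.na(D)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- matrix(0L, 4 * bytes_per_snp - n, m)
  codes <- rbind(code, pad)
  shifts <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
  for (j in seq_len(m)) {
    v <- codes[, j] * shifts
    byte_vals <- colSums(matrix(v, nrow = 4))
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' @rdname pipeline_io
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"),
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "snp_id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bytes_per_snp * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK bed file: ", prefix, ".bed")
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit pairs, least-significant pair first
  pairs <- rbind(body %% 4, (body %/% 4) %% 4,
                 (body %/% 16) %% 4, (body %/% 64) %% 4)
  codes <- matrix(as.vector(pairs), nrow = 4 * bytes_per_snp)[seq_len(n), ,
                                                              drop = FALSE]
  D <- matrix(NA_real_, n, m)
  D[codes == 0L] <- 2
  D[codes == 2L] <- 1
  D[codes == 3L] <- 0
  snps <- data.frame(snp_id = bim$snp_id,
                     chromosome = suppressWarnings(as.integer(bim$chr)),
                     position = bim$pos, ref_allele = bim$a2,
                     alt_allele = bim$a1, stringsAsFactors = FALSE)
  if (anyNA(snps$chromosome)) snps$chromosome <- bim$chr
  genotype_matrix(D, snps, fam$iid)
}

#' @rdname pipeline_io
#' @param genes gene annotation data.frame (`gene_id`, `chromosome`,
#'   `start`, `end`, 1-based inclusive).
#' @export
write_gene_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chromosome),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    name = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  chr <- as.character(GenomicRanges::seqnames(gr))
  chr_int <- suppressWarnings(as.integer(chr))
  genes <- data.frame(
    gene_id = gr$name,
    chromosome = if (anyNA(chr_int)) chr else chr_int,
    start = GenomicRanges::start(gr), # rtracklayer converts 0-based half-open
    end = GenomicRanges::end(gr),     # to 1-based inclusive on import
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in ", path)
  genes
}

#' @rdname pipeline_io
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT record at line ", i, ": fewer than 3 fields")
    }
    sets[[parts[1]]] <- parts[-(1:2)]
    desc[parts[1]] <- parts[2]
  }
  gene_set_collection(sets, desc)
}

#' @rdname pipeline_io
#' @param stats a `summary_stats` or `meta_result` data.frame.
#' @export
write_summary_tsv <- function(stats, path) {
  fwrite_exact(as.data.frame(stats), path)
}

#' @rdname pipeline_io
#' @export
read_summary_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("snp_id", "chr", "pos", "effect_allele", "other_allele", "eaf",
            "beta", "se", "z", "p", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("malformed summary TSV, missing column(s): ",
         paste(miss, collapse = ", "))
  }
  class(tab) <- c(if ("k_studies" %in% names(tab)) "meta_result",
                  "summary_stats", "data.frame")
  tab
}

#' @rdname pipeline_io
#' @param phenotypes list as returned by [simulate_phenotypes()] (battery,
#'   age, sex, sample_ids).
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  tab <- data.frame(sample_id = phenotypes$sample_ids,
                    phenotypes$battery,
                    age = phenotypes$age, sex = phenotypes$sex,
                    check.names = FALSE)
  fwrite_exact(tab, path)
}

#' @rdname pipeline_io
#' @export
read_phenotype_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("sample_id", "age", "sex") %in% names(tab)))
  test_cols <- setdiff(names(tab), c("sample_id", "age", "sex"))
  battery <- as.matrix(tab[, test_cols, drop = FALSE])
  rownames(battery) <- tab$sample_id
  list(battery = battery, age = tab$age, sex = tab$sex,
       sample_ids = tab$sample_id)
}

#' @rdname pipeline_io
#' @param scores named numeric vector of per-sample scores.
#' @export
write_scores_tsv <- function(scores, path) {
  fwrite_exact(data.frame(sample_id = names(scores), score = scores), path)
}

#' @rdname pipeline_io
#' @export
read_scores_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  stats::setNames(tab$score, tab$sample_id)
}

#' @rdname pipeline_io
#' @param results a `gene_results` or `enrichment_results` data.frame.
#' @export
write_results_tsv <- function(results, path) {
  fwrite_exact(as.data.frame(results), path)
}

#' @rdname pipeline_io
#' @param class_tag class to restore on read ("gene_results",
#'   "ranked_genes" or "enrichment_results").
#' @export
read_results_tsv <- function(path, class_tag = "gene_results") {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(tab) <- c(class_tag, "data.frame")
  tab
}
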