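#' Candidate gene-set bookkeeping: postsynaptic-density set sizes
#'
#' Published sizes of the six postsynaptic-density (PSD) candidate gene
#' sets, as total genes and the autosomal subset actually analysed
#' (X-chromosome genes are excluded from autosomal GWAS pipelines). The
#' table ships with the package; `autosomal_pct` recomputes the autosomal
#' percentage of each list from the counts.
#'
#' @return A data.frame: `set`, `n_total`, `n_autosomal`, `autosomal_pct`,
#'   `description`.
#' @export
#' @examples
#' psd_set_counts()[, c("set", "autosomal_pct")]
psd_set_counts <- function() {
  path <- system.file("extdata", "psd_gene_sets.tsv", package = "cogset",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$autosomal_pct <- autosomal_pct(tab$n_autosomal, tab$n_total)
  tab[, c("set", "n_total", "n_autosomal", "autosomal_pct", "description")]
}

#' @rdname psd_set_counts
#' @param n_autosomal,n_total gene counts (autosomal subset and full list).
#' @export
autosomal_pct <- function(n_autosomal, n_total) {
  stopifnot(all(n_total >= 1), all(n_autosomal >= 0),
            all(n_autosomal <= n_total))
  100 * n_autosomal / n_total
}
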