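#' Derive a reproducible child seed from a master seed and a key
#'
#' Every stochastic stage of the pipeline receives its own seed derived
#' deterministically from the run's master seed and a stage- or unit-specific
#' key (cohort index, gene id, stage name). Adding a cohort or a gene
#' therefore never perturbs the random stream of any other unit.
#'
#' @param master integer master seed.
#' @param key character or integer key identifying the unit.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "cohort1")
#' derive_seed(42, "geneG0001")
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master))
  txt <- paste(format(master, scientific = FALSE), as.character(key), sep = ":")
  bytes <- utf8ToInt(txt)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h) + 1L
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Standardize a numeric vector to mean 0, sd 1 (sample sd), preserving names.
# NAs are ignored in the moments and propagated in the output.
standardize <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    stop("cannot standardize: variance is (numerically) zero")
  }
  out <- (x - mu) / s
  names(out) <- names(x)
  out
}

# Clip p-values away from 0 and 1 before normal-quantile transforms.
clip_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) {
  if (any(p <= lo | p >= hi)) {
    warning("p-values clipped to (", lo, ", ", hi, ") before quantile transform")
  }
  pmin(pmax(p, lo), hi)
}
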