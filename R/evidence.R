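#' Bonferroni correction
#'
#' @param p P-value in `(0, 1]`.
#' @param m number of tests (integer >= 1).
#' @return `min(1, m * p)`.
#' @export
#' @examples
#' bonferroni(0.002, 20) # 0.04
bonferroni <- function(p, m) {
  if (length(m) != 1 || m < 1 || m != round(m)) {
    stop("m must be a single integer >= 1")
  }
  stopifnot(all(p > 0), all(p <= 1))
  pmin(1, m * p)
}

#' Stouffer's weighted-Z combination of one-sided P-values
#'
#' Each cohort's enrichment P is converted to an upper-tail standard-normal
#' quantile `Z_i = qnorm(1 - p_i)`; the combined statistic is
#' `Z = sum(w_i Z_i) / sqrt(sum(w_i^2))` with weights `w_i = sqrt(n_i)`
#' (so cohorts count by effective information), and the combined P is the
#' upper-tail probability of `Z`. Invariant to rescaling all weights.
#'
#' @param p numeric vector of one-sided P-values, strictly inside `(0, 1)`
#'   (values at the boundary are clipped with a warning).
#' @param n per-cohort sample sizes (positive; same length as `p`).
#' @return A list: `p_combined`, `z_combined`, and the per-cohort table
#'   `cohorts` (`p`, `n`, `z`, `weight`).
#' @export
#' @examples
#' stouffer_weighted(c(0.04, 0.012, 0.371), c(3511, 2062, 670))$p_combined
stouffer_weighted <- function(p, n) {
  stopifnot(length(p) >= 1, length(n) == length(p), all(n > 0))
  if (any(p <= 0 | p >= 1)) {
    stop("p must lie strictly inside (0, 1): 0 or 1 gives an infinite Z")
  }
  p <- clip_p(p) # guard the quantile transform against denormal extremes
  z <- stats::qnorm(p, lower.tail = FALSE)
  w <- sqrt(n)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(
    p_combined = stats::pnorm(zc, lower.tail = FALSE),
    z_combined = zc,
    cohorts = data.frame(p = p, n = n, z = z, weight = w)
  )
}
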