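#' First-unrotated-component factor scores from a test battery
#'
#' Extracts general-ability scores as the first principal component of the
#' battery's correlation matrix, regression-scored and standardized. Using
#' the correlation (not covariance) matrix makes the extraction invariant to
#' the scale of individual tests. The component is oriented so the mean test
#' loading is positive, which makes the sign stable across resamples of the
#' same generating process. Rows with any missing test are dropped from the
#' extraction (listwise deletion) and returned as `NA`.
#'
#' @param battery numeric samples x tests matrix (rownames = sample ids).
#' @return Named numeric vector of standardized scores (mean 0, sd 1 over
#'   non-missing entries).
#' @export
#' @examples
#' b <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("t1", "t2")))
#' s <- gf_scores(b)
#' c(mean(s), sd(s))
gf_scores <- function(battery) {
  stopifnot(is.matrix(battery), nrow(battery) >= 2, ncol(battery) >= 1)
  cn <- colnames(battery) %||% paste0("test_", seq_len(ncol(battery)))
  complete <- stats::complete.cases(battery)
  if (sum(complete) < 2) stop("fewer than 2 complete rows in battery")
  X <- battery[complete, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    stop("zero-variance test column: ", paste(cn[sds < .Machine$double.eps^0.5],
                                              collapse = ", "))
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (mean(v) < 0) v <- -v
  # regression scores for PCA: loadings-weighted standardized tests scaled by
  # the inverse eigenvalue; equals the standardized component score
  raw <- drop(Z %*% v) / eig$values[1]
  out <- rep(NA_real_, nrow(battery))
  out[complete] <- standardize(raw)
  names(out) <- rownames(battery)
  out
}

#' Residualize scores on age and sex
#'
#' Ordinary least-squares regression of the scores on age and sex; the
#' standardized residuals are returned. By construction they are exactly
#' uncorrelated with both covariates.
#'
#' @param scores numeric vector of phenotype scores.
#' @param age,sex numeric covariate vectors, same length as `scores`.
#' @return Named numeric vector of standardized residuals.
#' @export
residualize_age_sex <- function(scores, age, sex) {
  stopifnot(length(age) == length(scores), length(sex) == length(scores))
  ok <- stats::complete.cases(scores, age, sex)
  fit <- stats::lm.fit(cbind(1, age[ok], sex[ok]), scores[ok])
  r <- fit$residuals
  if (stats::var(r) < .Machine$double.eps) {
    stop("degenerate residuals: scores are an exact linear function of age and sex")
  }
  out <- rep(NA_real_, length(scores))
  out[ok] <- standardize(r)
  names(out) <- names(scores)
  out
}

#' Composite of two standardized phenotype scores
#'
#' Per-sample mean of two standardized score vectors, re-standardized: the
#' construction used for a general-ability composite built from a fluid
#' factor and a vocabulary score.
#'
#' @param scores_a,scores_b named numeric vectors over the same samples.
#' @return Named numeric vector of standardized composite scores.
#' @export
composite_mean <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("alignment error: score vectors differ in length")
  }
  if (!is.null(names(scores_a)) && !is.null(names(scores_b)) &&
      !identical(names(scores_a), names(scores_b))) {
    stop("alignment error: sample ids of the two scores differ")
  }
  m <- (scores_a + scores_b) / 2
  out <- standardize(m)
  names(out) <- names(scores_a)
  out
}
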