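#' PCA of binary appearance patterns
#'
#' Samples are observations, proteins are features. The binary matrix is
#' column-centered but not scaled (the variance of a Bernoulli feature is
#' informative), then decomposed by SVD. Component signs are fixed so that
#' each component's largest-magnitude loading is positive, making output
#' reproducible across BLAS implementations.
#'
#' @param a an [appearance_matrix()].
#' @param n_components number of components to return (default 3); must be
#'   smaller than the number of samples.
#' @return A list of class `binary_pca` with fields `sample_ids`,
#'   `coordinates` (n_samples x n_components score matrix),
#'   `explained_variance_fractions` (fractions of total variance,
#'   non-increasing), `loadings` (proteins x components) and `center`.
#' @export
pca_binary <- function(a, n_components = 3L) {
  stopifnot(inherits(a, "appearance_matrix"))
  X <- t(a$bits) * 1.0
  n <- nrow(X)
  if (n <= n_components)
    stop("need more samples (", n, ") than components (", n_components, ")")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  V <- sv$v
  scores <- Xc %*% V
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
    }
  }
  frac <- sv$d^2 / sum(sv$d^2)
  k <- seq_len(n_components)
  structure(list(sample_ids = a$sample_ids,
                 coordinates = scores[, k, drop = FALSE],
                 explained_variance_fractions = frac[k],
                 loadings = V[, k, drop = FALSE],
                 center = ctr),
            class = "binary_pca")
}

#' @export
print.binary_pca <- function(x, ...) {
  cat("binary_pca:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "components; explained",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Default p-value threshold grid
#'
#' 50 log-spaced thresholds spanning `[1e-4, 1]`.
#'
#' @return Ascending numeric vector in (0, 1].
#' @export
default_threshold_grid <- function() {
  10^seq(log10(1e-4), 0, length.out = 50L)
}

#' Observed/expected overabundance curve
#'
#' For each threshold `alpha`, counts the proteins with `p <= alpha`
#' (inclusive), the expected null count `alpha * m`, their ratio, and the
#' plug-in FDR estimate `expected / observed` capped at 1. Only defined
#' (non-`NA`) p-values contribute; `m` is their count.
#'
#' @param p_values numeric p-values; `NA` entries are dropped.
#' @param thresholds ascending grid in (0, 1]; default
#'   [default_threshold_grid()].
#' @return A data frame of class `overabundance_curve` with columns
#'   `threshold`, `observed`, `expected`, `ratio`, `fdr_estimate`
#'   (`NA` where observed is 0).
#' @export
overabundance <- function(p_values, thresholds = default_threshold_grid()) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no defined p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  thresholds <- sort(as.numeric(thresholds))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  m <- length(p)
  observed <- vapply(thresholds, function(a) sum(p <= a), 0L)
  expected <- thresholds * m
  out <- data.frame(threshold = thresholds, observed = observed,
                    expected = expected,
                    ratio = observed / expected,
                    fdr_estimate = ifelse(observed > 0,
                                          pmin(1, expected / observed),
                                          NA_real_))
  class(out) <- c("overabundance_curve", "data.frame")
  out
}

#' Plug-in FDR at a single p-value threshold
#'
#' `min(1, alpha * m / observed)` where `m` is the number of defined
#' p-values and `observed` the number at or below `alpha`; `NA` when nothing
#' is observed.
#'
#' @param p_values numeric p-values; `NA` entries are dropped.
#' @param alpha threshold in (0, 1].
#' @return A single number in (0, 1], or `NA` if `observed = 0`.
#' @export
fdr_at_threshold <- function(p_values, alpha) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha <= 1)
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no defined p-values")
  observed <- sum(p <= alpha)
  if (observed == 0L) return(NA_real_)
  min(1, alpha * length(p) / observed)
}
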