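#' Shrinkage estimate of the partial correlation matrix
#'
#' Estimates partial correlations between all protein pairs via the
#' Schaefer-Strimmer shrinkage covariance estimator: the sample correlation
#' matrix R is shrunk toward the identity, R* = lambda I + (1 - lambda) R,
#' with the analytic optimal shrinkage intensity
#' lambda = sum_{i != j} Var(r_ij) / sum_{i != j} r_ij^2 (clipped to [0, 1]).
#' R* is inverted and the negated inverse standardized to partial
#' correlations. With lambda > 0 the estimator is positive definite even when
#' proteins outnumber samples.
#'
#' @param mat Complete (no missing values) numeric samples x proteins matrix
#'   with dimnames; needs > 3 samples and >= 2 proteins.
#' @param lambda Optional shrinkage intensity override in [0, 1]; `NULL`
#'   (default) uses the analytic estimate. `lambda = 0` reduces to direct
#'   inversion of the sample correlation matrix and errors if that matrix is
#'   singular.
#' @return List with `pcor` (symmetric proteins x proteins matrix, unit
#'   diagonal) and `lambda` (the intensity used).
#' @export
estimate_pcor_shrinkage <- function(mat, lambda = NULL) {
  mat <- as_protein_matrix(mat)
  if (anyNA(mat)) stop("partial correlation estimation requires a complete matrix")
  n <- nrow(mat); p <- ncol(mat)
  if (n <= 3L) stop("need more than 3 samples")
  if (p < 2L) stop("need at least 2 proteins")
  xs <- scale(mat)          # unit-variance columns: cross-products give r
  R <- crossprod(xs) / (n - 1)
  if (is.null(lambda)) {
    # Var(r_ij) from the empirical variance of the standardized products
    # w_kij = x_ki * x_kj: var_r = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2
    sum_var <- 0; sum_r2 <- 0
    for (j in seq_len(p - 1L)) {
      wj <- xs[, j] * xs[, (j + 1L):p, drop = FALSE]
      wbar <- colMeans(wj)
      vr <- n / (n - 1)^3 * colSums(sweep(wj, 2L, wbar)^2)
      sum_var <- sum_var + sum(vr)
      sum_r2 <- sum_r2 + sum(R[j, (j + 1L):p]^2)
    }
    lambda <- if (sum_r2 > 0) min(1, max(0, sum_var / sum_r2)) else 1
  } else {
    stopifnot(length(lambda) == 1L, lambda >= 0, lambda <= 1)
  }
  Rstar <- (1 - lambda) * R
  diag(Rstar) <- 1
  omega <- tryCatch(solve(Rstar), error = function(e) {
    stop("shrunk correlation matrix is singular (lambda = ", lambda,
         "); use lambda > 0")
  })
  d <- 1 / sqrt(diag(omega))
  pcor <- -omega * outer(d, d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- list(colnames(mat), colnames(mat))
  list(pcor = pcor, lambda = lambda)
}

#' -log10 p-values for partial correlations via Fisher's z
#'
#' Tests each full-order partial correlation with the Fisher transform,
#' z = atanh(pcor) * sqrt(n - 3 - (p - 2)): conditioning on the other p - 2
#' variables costs p - 2 effective degrees of freedom relative to the
#' marginal-correlation test. The effective term under the square root is
#' floored at 3 so the statistic stays defined for p close to n.
#'
#' @param pcor Symmetric partial correlation matrix.
#' @param n Sample count used in the estimate (>= 10).
#' @param p Number of proteins conditioned on (defaults to `ncol(pcor)`).
#' @return Matrix of two-sided -log10 p-values (diagonal 0); entries with
#'   |pcor| = 1 get `Inf`.
#' @export
pcor_pvalues <- function(pcor, n, p = ncol(pcor)) {
  stopifnot(is.matrix(pcor), nrow(pcor) == ncol(pcor))
  if (n < 10) stop("'n' must be >= 10")
  kappa <- max(n - 3 - (p - 2), 3)
  out <- matrix(Inf, nrow(pcor), ncol(pcor), dimnames = dimnames(pcor))
  ok <- abs(pcor) < 1
  out[ok] <- neglog10_p_from_z(atanh(pcor[ok]) * sqrt(kappa))
  diag(out) <- 0
  out
}

#' Bonferroni-significant partial-correlation edges
#'
#' Flags edges whose two-sided p-value falls below
#' alpha / (n_proteins * (n_proteins - 1) / 2) — the Bonferroni correction
#' over all unordered protein pairs — and returns one row per unordered pair
#' sorted by -log10 p descending.
#'
#' @param pcor Symmetric partial correlation matrix with protein dimnames.
#' @param pvalues Matching matrix of -log10 p-values (from [pcor_pvalues()]).
#' @param n_proteins Number of proteins defining the Bonferroni family
#'   (default `ncol(pcor)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return data.frame with columns `proteinA`, `proteinB` (A < B
#'   lexicographically), `pcor`, `neglog10p`, `significant`; attribute
#'   `threshold` holds the per-test alpha.
#' @export
significant_edges <- function(pcor, pvalues, n_proteins = ncol(pcor),
                              alpha = 0.05) {
  stopifnot(is.matrix(pcor), identical(dim(pcor), dim(pvalues)))
  if (n_proteins < 2L) stop("'n_proteins' must be >= 2")
  threshold <- alpha / (n_proteins * (n_proteins - 1) / 2)
  ids <- colnames(pcor)
  ut <- upper.tri(pcor)
  idx <- which(ut, arr.ind = TRUE)
  a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(
    proteinA = a, proteinB = b,
    pcor = pcor[ut], neglog10p = pvalues[ut],
    significant = pvalues[ut] > -log10(threshold),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$neglog10p, edges$proteinA, edges$proteinB), ]
  rownames(edges) <- NULL
  attr(edges, "threshold") <- threshold
  edges
}
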