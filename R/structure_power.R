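#' Genotype PCA for population structure
#'
#' Missing dosages are mean-imputed per SNP; each SNP is centered at twice
#' its allele frequency and scaled by `sqrt(2 p (1 - p))` (the standard
#' standardization for genotype PCA), then the standardized matrix is
#' decomposed by SVD. SNPs monomorphic after imputation are dropped. The
#' sign of every component is fixed deterministically: the loading of
#' largest magnitude is made positive.
#'
#' @param geno a QC'd [genotype_matrix()].
#' @param k number of components (truncated to the matrix rank, with a
#'   warning, if larger).
#' @return list of class `genotype_pca`: `scores` (n x k), `loadings`
#'   (m x k), `varexp` (proportion of variance per component), `center`,
#'   `scale`, `snp_ids`.
#' @export
genotype_pca <- function(geno, k = 2L) {
  d <- geno$dosage
  storage.mode(d) <- "double"
  p_hat <- colMeans(d, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- 2 * p_hat[j]
  keep <- p_hat > 0 & p_hat < 1
  d <- d[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  Z <- sweep(d, 2L, 2 * p_hat, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p_hat * (1 - p_hat)), "/")
  sv <- svd(Z)
  pos <- sv$d > sv$d[1L] * 1e-12
  rank <- sum(pos)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (c0 in seq_len(k)) {
    i <- which.max(abs(loadings[, c0]))
    if (loadings[i, c0] < 0) {
      loadings[, c0] <- -loadings[, c0]
      scores[, c0] <- -scores[, c0]
    }
  }
  dimnames(scores) <- list(geno$samples, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(geno$snps$snp_id[keep], paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 varexp = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 center = 2 * p_hat,
                 scale = sqrt(2 * p_hat * (1 - p_hat)),
                 snp_ids = geno$snps$snp_id[keep]),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples x %d SNPs, %d components (%.1f%% var)\n",
              nrow(x$scores), length(x$snp_ids), ncol(x$scores),
              100 * sum(x$varexp)))
  invisible(x)
}

#' Cohen's h for two proportions
#'
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`.
#' @param p1,p2 proportions in \[0, 1\].
#' @return h (signed).
#' @export
cohen_h <- function(p1, p2) 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))

#' Analytic power of the two-proportion test at a standardized effect
#'
#' Normal-approximation power of the (arcsine-scale) two-proportion test for
#' Cohen's effect size h with unequal group sizes:
#' `power = Phi(h sqrt(ntilde / 2) - z) + Phi(-h sqrt(ntilde / 2) - z)` for
#' the two-sided test, with `ntilde = 2 n1 n2 / (n1 + n2)` the harmonic mean
#' sample size and `z` the upper alpha/2 normal quantile.
#'
#' @param h Cohen's standardized difference of proportions (> 0).
#' @param alpha significance level.
#' @param n1,n2 group sizes.
#' @param sided 2 (default) or 1.
#' @return power in (0, 1).
#' @export
two_proportion_power <- function(h, alpha = 0.05, n1, n2, sided = 2L) {
  stopifnot(h >= 0, alpha > 0, alpha < 1, n1 >= 1, n2 >= 1)
  ntilde <- 2 * n1 * n2 / (n1 + n2)
  a <- h * sqrt(ntilde / 2)
  if (sided == 2L) {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(a - z) + stats::pnorm(-a - z)
  } else {
    stats::pnorm(a - stats::qnorm(1 - alpha))
  }
}
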