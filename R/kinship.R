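#' Inverse local-LD weights per SNP
#'
#' Down-weights SNPs in strong local linkage so that clusters of linked
#' sites do not dominate the kinship matrix:
#' \deqn{w_j = 1 / (1 + \sum_{k \ne j,\ |pos_k - pos_j| \le W} r^2_{jk})}
#' with the sum over same-arm neighbours within `window_bp`. An isolated
#' SNP gets weight 1; a pair in perfect LD gets 1/2 each; a duplicated
#' triple 1/3 each.
#'
#' @param panel a `genotype_panel` (MAF-filtered; missing calls are
#'   mean-imputed for the correlation).
#' @param window_bp neighbourhood for the r-squared sum (default 100000).
#' @return numeric weights in (0, 1], one per site.
#' @export
ld_weights <- function(panel, window_bp = 100000) {
  G <- impute_mean(panel$geno)
  m <- ncol(G)
  w <- numeric(m)
  for (arm in unique(panel$sites$arm)) {
    idx <- which(panel$sites$arm == arm)
    pos <- panel$sites$pos[idx]
    Ga <- scale(G[, idx, drop = FALSE])
    n1 <- nrow(Ga) - 1L
    ssum <- numeric(length(idx))
    lo <- 1L
    for (k in seq_along(idx)) {
      while (pos[k] - pos[lo] > window_bp) lo <- lo + 1L
      if (lo < k) {
        r <- crossprod(Ga[, lo:(k - 1L), drop = FALSE], Ga[, k]) / n1
        r2 <- r^2
        ssum[k] <- ssum[k] + sum(r2)
        ssum[lo:(k - 1L)] <- ssum[lo:(k - 1L)] + r2
      }
    }
    w[idx] <- 1 / (1 + ssum)
  }
  w
}

#' LD- and MAF-weighted kinship matrix
#'
#' Builds \eqn{K = ZZ'/c} where column \eqn{j} of \eqn{Z} is
#' \eqn{\sqrt{w_j}\,(x_j - p_j)\,[p_j(1-p_j)]^{\alpha/2}} for allele dose
#' \eqn{x_j}, allele frequency \eqn{p_j}, LD weight \eqn{w_j}, and MAF
#' exponent \eqn{\alpha} (default -0.25, a milder MAF standardisation than
#' the human-genetics default of -1, which recovers the fully standardised
#' kinship). The constant \eqn{c} normalises the mean diagonal to 1.
#' Missing genotypes are mean-imputed per SNP.
#'
#' @param panel a `genotype_panel`.
#' @param weights per-SNP LD weights (default: equal).
#' @param alpha MAF exponent (default -0.25).
#' @return list of class `kinship_model`: `K` (symmetric PSD, mean diag 1),
#'   `ld_weights`, `alpha`, `scale_c`.
#' @export
kinship <- function(panel, weights = NULL, alpha = -0.25) {
  G <- impute_mean(panel$geno)
  p <- colMeans(G)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic column in the genotype matrix; apply the MAF filter first")
  m <- ncol(G)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0))
  Z <- sweep(G, 2L, p) *
    rep(sqrt(weights) * (p * (1 - p))^(alpha / 2), each = nrow(G))
  K <- tcrossprod(Z)
  c_ <- mean(diag(K))
  K <- K / c_
  structure(list(K = K, ld_weights = weights, alpha = alpha, scale_c = c_),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat(sprintf("Kinship model: %d individuals, alpha = %.2f, mean diag %.3f\n",
              nrow(x$K), x$alpha, mean(diag(x$K))))
  invisible(x)
}
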