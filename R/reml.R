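#' SNP heritability by REML with a single kinship component
#'
#' Fits \eqn{y \sim N(0, \sigma^2_{SNP} K + \sigma^2_e I)} to a centred
#' phenotype by maximising the likelihood profile over the variance ratio
#' \eqn{\gamma = \sigma^2_{SNP}/\sigma^2_e} on the eigenbasis of `K`
#' (the residual variance has a closed form given \eqn{\gamma}). With no
#' fixed effects and a pre-centred phenotype this coincides with REML.
#' SNP heritability is \eqn{h^2_{SNP} = \sigma^2_{SNP} /
#' (\sigma^2_{SNP} + \sigma^2_e)}.
#'
#' @param y numeric phenotype (centred internally).
#' @param K kinship matrix or `kinship_model`.
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)`; pass it
#'   when fitting many phenotypes against one kinship.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @return list: `h2_snp`, `sigma2_snp`, `sigma2_e`, `logLik`.
#' @export
reml_h2 <- function(y, K, eig = NULL, tol = 1e-8) {
  if (inherits(K, "kinship_model")) K <- K$K
  y <- y - mean(y)
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-6 * max(abs(lam))) stop("kinship matrix is not positive semi-definite")
  lam <- pmax(lam, 0)
  yt2 <- as.numeric(crossprod(eig$vectors, y))^2

  nll <- function(log_gamma) {
    g <- exp(log_gamma)
    d <- g * lam + 1
    s2e <- sum(yt2 / d) / n
    0.5 * (n * log(s2e) + sum(log(d)) + n)
  }
  opt <- stats::optimize(nll, c(-25, 25), tol = tol)
  # compare against the boundary gamma -> 0 (pure noise)
  if (nll(-25) <= opt$objective + tol) opt <- list(minimum = -25, objective = nll(-25))
  g <- exp(opt$minimum)
  d <- g * lam + 1
  s2e <- sum(yt2 / d) / n
  s2g <- g * s2e
  list(h2_snp = s2g / (s2g + s2e), sigma2_snp = s2g, sigma2_e = s2e,
       logLik = -opt$objective - 0.5 * n * log(2 * pi))
}

#' Permutation significance of a SNP-heritability estimate
#'
#' Permutes phenotype labels `n_perm` times, re-estimates h2_SNP on each
#' permutation, and reports
#' \eqn{p = (1 + \#\{\hat h^2_{perm} \ge \hat h^2_{obs}\}) / (1 + n_{perm})}.
#'
#' @param y phenotype; `K` kinship (matrix or model); `n_perm` permutations.
#' @param K kinship matrix or model.
#' @param n_perm number of permutations (default 1000; must be >= 1).
#' @param seed RNG seed for the permutations.
#' @return list: `p`, `observed`, `perm` (the permuted estimates).
#' @export
permutation_pvalue_h2 <- function(y, K, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (inherits(K, "kinship_model")) K <- K$K
  eig <- eigen(K, symmetric = TRUE)
  obs <- reml_h2(y, K, eig = eig)$h2_snp
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    reml_h2(sample(y), K, eig = eig)$h2_snp, numeric(1))
  list(p = (1 + sum(perm >= obs)) / (1 + n_perm), observed = obs, perm = perm)
}

#' Multi-component REML over several kinship matrices
#'
#' Maximises the likelihood of \eqn{y \sim N(0, \sum_c \sigma^2_c K_c +
#' \sigma^2_e I)} over log-scale variance components by Nelder-Mead.
#' Used by the heritability partition and the window set-test.
#'
#' @param y centred phenotype.
#' @param Ks list of kinship matrices (each mean-diagonal-normalised).
#' @param hessian return the Hessian of the negative log-likelihood in
#'   log-variance coordinates (for delta-method SEs).
#' @return list: `sigma2` (named per component + `e`), `logLik`, and
#'   optionally `hessian`.
#' @export
reml_multi <- function(y, Ks, hessian = FALSE) {
  y <- y - mean(y)
  n <- length(y)
  C <- length(Ks)
  v0 <- stats::var(y)
  nll <- function(ltheta) {
    s2 <- exp(ltheta)
    V <- diag(s2[C + 1L], n)
    for (c_ in seq_len(C)) V <- V + s2[c_] * Ks[[c_]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    u <- backsolve(ch, y, transpose = TRUE)
    sum(log(diag(ch))) + 0.5 * sum(u^2)
  }
  start <- log(rep(v0 / (C + 1L), C + 1L))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  s2 <- exp(opt$par)
  names(s2) <- c(names(Ks) %||% paste0("K", seq_len(C)), "e")
  out <- list(sigma2 = s2,
              logLik = -opt$value - 0.5 * n * log(2 * pi))
  if (hessian)
    out$hessian <- stats::optimHess(opt$par, nll)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
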