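#' Partition SNP heritability across SNP classes
#'
#' Fits one kinship per class jointly,
#' \eqn{y \sim N(0, \sum_c \sigma^2_c K_c + \sigma^2_e I)}, and reports
#' each class's share of total SNP heritability
#' (\eqn{\sigma^2_c / \sum_{c'} \sigma^2_{c'}}) against its expected share
#' — the class's fraction of LD-weight mass among predictors (SNP fraction
#' when weights are equal). Deviations are tested with a two-sample Z-test
#' using the delta-method SE of the observed share.
#'
#' @param y phenotype (one per line).
#' @param panel a `genotype_panel`.
#' @param classes factor/character per SNP; must cover all SNPs.
#' @param weights optional per-SNP LD weights (expected shares use them).
#' @param alpha MAF exponent for the class kinships (default -0.25).
#' @param min_snps classes below this size are flagged unstable
#'   (default 10).
#' @return `partition_result` data.frame: `class`, `n_snps`, `share`
#'   (observed), `expected`, `se`, `z`, `p`, `unstable`. Attribute
#'   `"sigma2"` carries the raw components.
#' @export
partition_h2 <- function(y, panel, classes, weights = NULL, alpha = -0.25,
                         min_snps = 10L) {
  classes <- as.character(classes)
  stopifnot(length(classes) == ncol(panel$geno))
  if (anyNA(classes)) stop("classes must cover every SNP")
  y <- y - mean(y)
  cls <- sort(unique(classes))
  if (is.null(weights)) weights <- rep(1, length(classes))

  Ks <- lapply(cls, function(cl) {
    idx <- which(classes == cl)
    sub <- subset_sites(panel, idx)
    kinship(sub, weights = weights[idx], alpha = alpha)$K
  })
  names(Ks) <- cls
  fit <- reml_multi(y, Ks, hessian = TRUE)
  C <- length(cls)
  s2 <- fit$sigma2[seq_len(C)]
  total <- sum(s2)
  share <- s2 / total

  # delta method: cov(log s2) ~ H^{-1}; share gradient wrt log s2
  se <- rep(NA_real_, C)
  covl <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(covl)) {
    for (c_ in seq_len(C)) {
      grad <- -share[c_] * s2 / total
      grad[c_] <- grad[c_] + s2[c_] / total
      g <- c(grad, 0)                        # residual log-variance slot
      v <- as.numeric(t(g) %*% covl %*% g)
      se[c_] <- sqrt(max(v, 0))
    }
  }
  expected <- vapply(cls, function(cl) sum(weights[classes == cl]), numeric(1)) /
    sum(weights)
  z <- (share - expected) / se
  out <- data.frame(class = cls,
                    n_snps = as.integer(table(factor(classes, levels = cls))),
                    share = share, expected = expected, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    unstable = as.integer(table(factor(classes, levels = cls))) < min_snps,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sigma2") <- fit$sigma2
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Circular-permutation null for class heritability shares
#'
#' Rotates the genome-wide annotation vector (sites in arm/position order)
#' by a random offset per permutation — preserving the order of
#' annotations, their counts, and the LD structure of the genotypes —
#' then recomputes per-class heritability shares. Two-tailed empirical
#' p-values compare each class's observed deviation from its expected
#' share with the permuted deviations.
#'
#' @param y phenotype; `panel`, `classes`, `weights`, `alpha` as in
#'   [partition_h2()].
#' @param panel a `genotype_panel`.
#' @param classes per-SNP class labels in site order.
#' @param n_perm number of rotations (default 1000).
#' @param weights optional LD weights.
#' @param alpha MAF exponent.
#' @param seed RNG seed.
#' @param offsets optional explicit rotation offsets (overrides `n_perm`);
#'   offset 0 reproduces the observed partition exactly.
#' @return data.frame: `class`, `share`, `expected`, `p_circular`.
#' @export
circular_permutation_null <- function(y, panel, classes, n_perm = 1000L,
                                      weights = NULL, alpha = -0.25,
                                      seed = 1L, offsets = NULL) {
  m <- ncol(panel$geno)
  classes <- as.character(classes)
  obs <- partition_h2(y, panel, classes, weights, alpha)
  if (is.null(offsets)) {
    set.seed(seed)
    offsets <- sample.int(m, n_perm, replace = TRUE)
  }
  stat_obs <- obs$share - obs$expected
  cls <- obs$class
  perm_stats <- matrix(NA_real_, length(offsets), length(cls))
  for (i in seq_along(offsets)) {
    rot <- rotate_vector(classes, offsets[i])
    pr <- partition_h2(y, panel, rot, weights, alpha)
    perm_stats[i, ] <- pr$share[match(cls, pr$class)] -
      pr$expected[match(cls, pr$class)]
  }
  p <- vapply(seq_along(cls), function(c_)
    (1 + sum(abs(perm_stats[, c_]) >= abs(stat_obs[c_]), na.rm = TRUE)) /
      (1 + nrow(perm_stats)), numeric(1))
  data.frame(class = cls, share = obs$share, expected = obs$expected,
             p_circular = p, stringsAsFactors = FALSE)
}

#' Rotate a vector circularly by `k` positions
#' @param x vector; `k` non-negative offset.
#' @param k offset.
#' @return rotated vector (same multiset of values).
#' @export
rotate_vector <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1:(n - k)])
}

#' Two-proportion Z enrichment of candidates in a category
#'
#' Compares the proportion of candidate SNPs mapping to a category with
#' the proportion of all SNPs mapping to it, using a pooled-variance
#' two-proportion Z-test.
#'
#' @param candidate logical per SNP.
#' @param category logical per SNP (one category at a time) or a
#'   factor/character vector (then all categories are tested).
#' @return data.frame: `category`, `obs_prop` (among candidates),
#'   `exp_prop` (among all SNPs), `z`, `p`.
#' @export
category_enrichment_z <- function(candidate, category) {
  if (!is.logical(category)) {
    cats <- sort(unique(as.character(category)))
    return(do.call(rbind, lapply(cats, function(cl) {
      r <- category_enrichment_z(candidate, as.character(category) == cl)
      r$category <- cl
      r
    })))
  }
  n1 <- sum(candidate)
  n2 <- length(candidate)
  x1 <- sum(candidate & category)
  x2 <- sum(category)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  data.frame(category = NA_character_, obs_prop = p1, exp_prop = p2, z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}
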