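# Shared fixtures and independent oracles. Oracles are deliberately
# written as literal, loop-based transcriptions of the defining formulas,
# independent of the package's vectorised implementations.

small_cfg <- function(...) {
  defaults <- list(n_lines = 60L, snps_per_arm = 60L, arms = c("2L", "X"),
                   arm_length_bp = 60000L, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built haploid panel with independent Bernoulli sites
toy_panel <- function(n, m, seed = 1, p = NULL, arm = "2L", pos = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  if (is.null(pos)) pos <- sort(sample.int(m * 1000L, m))
  sites <- data.frame(arm = rep(arm, length.out = m), pos = pos,
                      ref = rep("A", m), alt = rep("T", m),
                      stringsAsFactors = FALSE)
  antagwas:::new_genotype_panel(sprintf("L%03d", seq_len(n)), sites, g)
}

## --- oracles --------------------------------------------------------

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# Tajima's D from an alignment matrix, via explicit pairwise differences
oracle_tajima_d <- function(H) {
  n <- nrow(H)
  S <- 0L
  for (j in seq_len(ncol(H))) {
    cnt <- sum(H[, j])
    if (cnt > 0 && cnt < n) S <- S + 1L
  }
  if (S == 0L) return(NA_real_)
  k <- 0
  npair <- 0
  for (i in 1:(n - 1)) for (l in (i + 1):n) {
    k <- k + sum(H[i, ] != H[l, ])
    npair <- npair + 1
  }
  pi <- k / npair
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hudson F_ST for one site, literal formula
oracle_hudson_site <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

# tissue-specificity index, literal formula
oracle_tau <- function(x) {
  xh <- x / max(x)
  s <- 0
  for (i in seq_along(x)) s <- s + (1 - xh[i])
  s / (length(x) - 1)
}

# per-SNP OLS Wald test via lm()
oracle_ols <- function(y, x) {
  fit <- summary(lm(y ~ x))
  co <- fit$coefficients
  c(beta = co[2, 1], se = co[2, 2], chi2 = co[2, 3]^2,
    p = pchisq(co[2, 3]^2, 1, lower.tail = FALSE))
}

# check the clump definition directly: every member is within dist of its
# index, in LD with it, and every unclaimed eligible SNP is justified
oracle_clump_valid <- function(cl, assoc, panel, p_index_max, r2_min,
                               dist_bp) {
  G <- antagwas:::impute_mean(panel$geno)
  for (cid in seq_len(cl$n_clusters)) {
    i <- cl$index[cid]
    members <- setdiff(which(cl$cluster == cid), i)
    for (j in members) {
      if (panel$sites$arm[j] != panel$sites$arm[i]) return(FALSE)
      if (abs(panel$sites$pos[j] - panel$sites$pos[i]) > dist_bp) return(FALSE)
      if (cor(G[, i], G[, j])^2 <= r2_min) return(FALSE)
    }
  }
  # no unclaimed SNP below the index threshold may remain
  un <- which(is.na(cl$cluster) & assoc$p <= p_index_max)
  length(un) == 0L
}

# one-way ANOVA estimate of hemiclonal h2 from normalised vial data
anova_h2 <- function(z, line, k_formula = 2) {
  f <- factor(line)
  fit <- anova(lm(z ~ f))
  msb <- fit$`Mean Sq`[1]
  msw <- fit$`Mean Sq`[2]
  nrep <- mean(table(f))
  s_g <- max((msb - msw) / nrep, 0)
  k_formula * s_g / (s_g + msw)
}
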