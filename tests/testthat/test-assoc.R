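test_that("LD weights follow the inverse-sum formula", {
  # isolated SNPs -> weight 1 (far apart)
  p <- toy_panel(100, 3, seed = 40, pos = c(1000L, 300000L, 700000L))
  expect_equal(ld_weights(p), rep(1, 3), tolerance = 1e-9)

  # perfect pair -> 1/2 each; duplicated triple -> 1/3 each
  set.seed(41)
  g <- rbinom(200, 1, 0.4)
  p2 <- toy_panel(200, 5, seed = 41, pos = c(100L, 200L, 5000L, 5100L, 5200L))
  p2$geno[, 1] <- g; p2$geno[, 2] <- g
  h <- rbinom(200, 1, 0.3)
  for (j in 3:5) p2$geno[, j] <- h
  w <- ld_weights(p2, window_bp = 500)
  expect_equal(w[1:2], c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(w[3:5], rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("kinship matrix has the stated structure", {
  p <- toy_panel(30, 400, seed = 42, p = runif(400, 0.3, 0.5))
  p$geno[2, ] <- p$geno[1, ]               # two identical lines
  km <- kinship(p)
  expect_equal(mean(diag(km$K)), 1, tolerance = 1e-12)
  expect_equal(km$K[1, 2], km$K[1, 1], tolerance = 1e-12)
  expect_true(isSymmetric(km$K))
  expect_gte(min(eigen(km$K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # alpha = -1 equals the fully standardised kinship
  km1 <- kinship(p, alpha = -1)
  G <- p$geno
  Zs <- scale(G, center = TRUE, scale = FALSE)
  ps <- colMeans(G)
  Zs <- sweep(Zs, 2L, sqrt(ps * (1 - ps)), "/")
  Ko <- tcrossprod(Zs); Ko <- Ko / mean(diag(Ko))
  expect_equal(km1$K, Ko, tolerance = 1e-10)

  # independent genotypes, many SNPs -> small off-diagonals
  pind <- toy_panel(20, 5000, seed = 43, p = runif(5000, 0.35, 0.5))
  kmi <- kinship(pind)
  expect_lt(max(abs(kmi$K[lower.tri(kmi$K)])), 0.15)

  pm <- toy_panel(10, 3, seed = 44)
  pm$geno[, 1] <- 1L
  expect_error(kinship(pm), "monomorphic")
})

test_that("single-component REML behaves at the limits", {
  cfg <- sim_config(n_lines = 200L, snps_per_arm = 250L,
                    arms = c("2L", "2R"), seed = 60L)
  K <- kinship(simulate_genotypes(cfg))$K
  eg <- eigen(K, symmetric = TRUE)
  # pure noise -> near-zero heritability (median over seeds)
  h2 <- sapply(1:20, function(i) {
    set.seed(i); reml_h2(rnorm(200), K, eig = eg)$h2_snp
  })
  expect_lte(median(h2), 0.1)

  # simulated h2 = 0.5 recovered
  h2r <- sapply(1:10, function(i) {
    set.seed(1000 + i)
    g <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(200))
    y <- sqrt(0.5) * g / sd(g) + rnorm(200) * sqrt(0.5)
    reml_h2(y, K, eig = eg)$h2_snp
  })
  expect_lt(abs(median(h2r) - 0.5), 0.15)

  # top eigenvector, no noise -> h2 -> 1
  ytop <- eg$vectors[, 1]
  expect_gt(reml_h2(ytop, K, eig = eg)$h2_snp, 0.99)
})

test_that("permutation p-value follows the +1 formula", {
  cfg <- sim_config(n_lines = 80L, snps_per_arm = 150L, arms = "2L",
                    seed = 61L)
  K <- kinship(simulate_genotypes(cfg))$K
  y <- eigen(K, symmetric = TRUE)$vectors[, 1]   # maximally heritable
  r <- permutation_pvalue_h2(y, K, n_perm = 50, seed = 2)
  expect_equal(r$p, 1 / 51)
  expect_error(permutation_pvalue_h2(y, K, n_perm = 0), "n_perm")
})

test_that("with K = I the mixed model equals the OLS oracle", {
  set.seed(47)
  n <- 50
  p <- toy_panel(n, 30, seed = 47)
  y <- rnorm(n)
  fit <- gwas_lmm(y, p, diag(n))
  for (j in c(1, 7, 19, 30)) {
    x <- p$geno[, j]
    x <- if (mean(x) > 0.5) 1 - x else x
    o <- oracle_ols(y, x)
    expect_equal(fit$result$beta[j], unname(o["beta"]), tolerance = 1e-8)
    expect_equal(fit$result$se[j], unname(o["se"]), tolerance = 1e-8)
    expect_equal(fit$result$p[j], unname(o["p"]), tolerance = 1e-8)
  }
})

test_that("constant SNPs are skipped with a record", {
  p <- toy_panel(40, 10, seed = 48)
  p$geno[, 4] <- 1L
  fit <- gwas_lmm(rnorm(40), p, diag(40))
  expect_true(4 %in% fit$skipped)
  expect_true(is.na(fit$result$p[4]))
})

test_that("inflation factor matches its definition", {
  p_unif <- (1:9999) / 10000
  expect_equal(inflation_factor(p_unif), 1, tolerance = 1e-3)
  expect_gt(inflation_factor(p_unif / 2), 1)
  # 5-value hand oracle
  pv <- c(0.01, 0.2, 0.5, 0.7, 0.9)
  chi <- qchisq(pv, 1, lower.tail = FALSE)
  expect_equal(inflation_factor(pv), median(chi) / qchisq(0.5, 1))
})

test_that("BH q-values equal the step-up oracle", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.37), 0.37)
  set.seed(49)
  for (i in 1:100) {
    pv <- runif(sample(3:50, 1))^sample(1:3, 1)
    q <- bh_qvalues(pv)
    expect_equal(q, oracle_bh(pv), tolerance = 1e-12)
    expect_equal(q, p.adjust(pv, "BH"), tolerance = 1e-12)
    expect_false(is.unsorted(q[order(pv)]))  # monotone in p
  }
})

test_that("whitening permutation reduces to plain permutation under K = I", {
  set.seed(50)
  n <- 60
  p <- toy_panel(n, 40, seed = 50)
  y <- rnorm(n)
  fit <- gwas_lmm(y, p, diag(n))
  pe <- whitening_permutation(fit, p, n_perm = 400, seed = 3)
  expect_gte(min(pe), 1 / 401)              # smallest attainable p
  expect_lte(max(pe), 1)
  # concordance with parametric p on a structured panel
  cfg <- small_cfg(n_lines = 100L, snps_per_arm = 100L)
  ps <- simulate_genotypes(cfg)
  f <- simulate_fitness(ps, cfg)
  lf <- fitness_pipeline(f$assays)
  panel2 <- antagwas:::new_genotype_panel(lf$line, ps$sites,
                                          ps$geno[match(lf$line, ps$lines), ])
  km <- kinship(panel2)
  fit2 <- gwas_lmm(lf$antagonism_index, panel2, km)
  pe2 <- whitening_permutation(fit2, panel2, n_perm = 1000, seed = 4)
  expect_gt(cor(fit2$result$p, pe2), 0.95)
})
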