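test_that("heritability partition shares behave and sum to one", {
  cfg <- small_cfg(n_lines = 100L, snps_per_arm = 80L, seed = 80L)
  p <- simulate_genotypes(cfg)
  f <- simulate_fitness(p, cfg)
  lf <- fitness_pipeline(f$assays)
  panel <- antagwas:::new_genotype_panel(lf$line, p$sites,
                                         p$geno[match(lf$line, p$lines), ])
  y <- lf$antagonism_index
  cls <- ifelse(panel$sites$arm == "X", "X", "autosome")
  part <- partition_h2(y, panel, cls)
  expect_equal(sum(part$share), 1, tolerance = 1e-6)
  expect_equal(sum(part$expected), 1, tolerance = 1e-12)
  expect_false(any(part$unstable))

  # single-class partition -> share = 1
  p1 <- partition_h2(y, panel, rep("all", ncol(panel$geno)))
  expect_equal(p1$share, 1, tolerance = 1e-9)
})

test_that("concentrating causal variation on one arm raises its share", {
  cfg <- small_cfg(n_lines = 120L, snps_per_arm = 80L, seed = 81L,
                   n_concordant_causal = 0L)
  p <- simulate_genotypes(cfg)
  # phenotype driven only by arm-2L SNPs
  idx2L <- which(p$sites$arm == "2L")
  set.seed(82)
  causal <- sample(idx2L, 15)
  y <- as.numeric(p$geno[, causal] %*% rnorm(15, sd = 1)) + rnorm(120, sd = 0.7)
  part <- partition_h2(y, p, ifelse(p$sites$arm == "2L", "2L", "other"))
  expect_gt(part$share[part$class == "2L"], part$expected[part$class == "2L"])
})

test_that("circular rotation preserves labels and offset zero is identity", {
  x <- c("a", "a", "b", "c", "c", "c")
  expect_identical(rotate_vector(x, 0), x)
  r <- rotate_vector(x, 2)
  expect_identical(sort(r), sort(x))
  expect_identical(r, c("c", "c", "a", "a", "b", "c"))

  cfg <- small_cfg(n_lines = 80L, snps_per_arm = 40L, seed = 83L)
  p <- simulate_genotypes(cfg)
  set.seed(84)
  y <- rnorm(80)
  cls <- sample(c("coding", "noncoding"), 80, replace = TRUE)
  r0 <- circular_permutation_null(y, p, cls, offsets = c(0L, 13L))
  obs <- partition_h2(y, p, cls)
  # offset 0 reproduces the observed shares, so p is bounded below 1
  expect_equal(r0$share, obs$share, tolerance = 1e-9)
})

test_that("two-proportion enrichment Z matches the hand formula", {
  # identical proportions -> Z = 0
  cand <- rep(c(TRUE, FALSE), c(100, 900))
  cat_flag <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 80, 180, 720))
  r <- category_enrichment_z(cand, cat_flag)
  expect_equal(r$z, 0, tolerance = 1e-12)

  # toy: 20/100 candidates vs 50/1000 overall
  cand2 <- rep(c(TRUE, FALSE), c(100, 900))
  cat2 <- c(rep(c(TRUE, FALSE), c(20, 80)), rep(c(TRUE, FALSE), c(30, 870)))
  r2 <- category_enrichment_z(cand2, cat2)
  p1 <- 0.2; p2 <- 0.05; pp <- (20 + 50) / (100 + 1000)
  z_hand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 1000))
  expect_equal(r2$z, z_hand, tolerance = 1e-12)

  # category absent among candidates -> negative Z
  cand3 <- rep(c(TRUE, FALSE), c(50, 950))
  cat3 <- c(rep(FALSE, 50), rep(c(TRUE, FALSE), c(100, 850)))
  expect_lt(category_enrichment_z(cand3, cat3)$z, 0)
})

test_that("sex-bias class test reproduces the deficit arithmetic", {
  r <- sexbias_class_test(observed = 188, expected = 212)
  expect_equal(r$deficit_pct, 100 * (212 - 188) / 212, tolerance = 1e-12)
  expect_equal(round(r$deficit_pct, 1), 11.3)

  r0 <- sexbias_class_test(observed = 50, expected = 50,
                           n_antagonistic = 100)
  expect_equal(r0$chi2, 0)

  # chi-squared equals the sum (O-E)^2/E over both cells
  rt <- sexbias_class_test(observed = 30, expected = 40,
                           n_antagonistic = 100)
  hand <- (30 - 40)^2 / 40 + (70 - 60)^2 / 60
  expect_equal(rt$chi2, hand, tolerance = 1e-12)
})

test_that("tau matches its formula and invariances", {
  expect_equal(tau(rep(5, 8)), 0)
  expect_equal(tau(c(0, 0, 7, 0)), 1)
  expect_equal(tau(c(4, 2, 2, 0)), 2 / 3, tolerance = 1e-12)
  set.seed(85)
  for (i in 1:20) {
    x <- rgamma(6, 2)
    expect_equal(tau(x), oracle_tau(x), tolerance = 1e-12)
    expect_equal(tau(x * 13.7), tau(x), tolerance = 1e-12)
  }
  expect_warning(tau(c(0, 0, 0)), "all-zero")
  expect_error(tau(5), "2 tissues")
})

test_that("PPI quasipoisson GLM detects rate differences", {
  set.seed(86)
  flag <- rep(c(TRUE, FALSE), each = 250)
  counts <- rnbinom(500, mu = ifelse(flag, 12, 6), size = 2)
  r <- ppi_glm(counts, flag)
  expect_lt(r$p, 0.01)
  expect_gt(r$coef, 0)
  expect_gt(r$dispersion, 1)
  expect_error(ppi_glm(rep(3L, 20), rep(c(TRUE, FALSE), 10)),
               "zero-variance")
})

test_that("overlap chi-squared equals the 2x2 oracle", {
  r <- overlap_chisq(50, 60, 1000, 10)
  expect_equal(r$expected, 3)
  tab <- matrix(c(10, 40, 50, 900), 2)
  expect_equal(r$chi2,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE))$statistic),
               tolerance = 1e-12)
  # disjoint small sets in a big background: tiny statistic
  r2 <- overlap_chisq(5, 5, 10000, 0)
  expect_lt(r2$chi2, 0.1)
})

test_that("gene table flags genes near candidate SNPs", {
  cfg <- small_cfg(seed = 87L)
  p <- simulate_genotypes(cfg)
  ann <- simulate_annotations(p, cfg)
  cand <- logical(nrow(p$sites))
  cand[10] <- TRUE
  gt <- build_gene_table(ann, p$sites, cand)
  near <- ann$genes$arm == p$sites$arm[10] &
    ann$genes$start - 5000 <= p$sites$pos[10] &
    ann$genes$end + 5000 >= p$sites$pos[10]
  expect_equal(gt$antagonistic, near)
  expect_true(all(gt$tau >= 0 & gt$tau <= 1, na.rm = TRUE))
})

test_that("quantitative sex-bias analyses find a peak at zero bias", {
  set.seed(88)
  n <- 2000
  bias <- c(rnorm(n / 2, 0, 0.2), rnorm(n / 2, 0, 1.5))
  prob <- plogis(-1 - 2 * abs(bias))        # antagonism peaks at no bias
  gt <- data.frame(log2_mf = bias, antagonistic = runif(n) < prob)
  r <- suppressWarnings(sexbias_quantitative(gt))
  expect_lt(r$wilcox$p, 0.01)
  expect_equal(r$quartic$df, 2L)
  expect_true(r$quartic$p > 0 && r$quartic$p <= 1)
})
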