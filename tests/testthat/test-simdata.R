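test_that("generators are pure functions of config and seed", {
  cfg <- small_cfg()
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$sites, p2$sites)
  f1 <- simulate_fitness(p1, cfg)
  f2 <- simulate_fitness(p2, cfg)
  expect_identical(f1$assays, f2$assays)
  a1 <- simulate_annotations(p1, cfg)
  a2 <- simulate_annotations(p2, cfg)
  expect_identical(a1$site_category, a2$site_category)
  expect_identical(a1$tissue_expr, a2$tissue_expr)
  c1 <- simulate_comparison_panel(p1, cfg)
  c2 <- simulate_comparison_panel(p2, cfg)
  expect_identical(c1$haplotypes, c2$haplotypes)
})

test_that("LD structure follows the configured block length", {
  cfg <- small_cfg(n_lines = 120L, snps_per_arm = 120L, arms = "2L",
                   arm_length_bp = 40000L)
  p <- simulate_genotypes(cfg)
  # brute-force r2 over all pairs within 1 kb and beyond
  pos <- p$sites$pos
  near <- c(); far <- c()
  for (i in 1:(length(pos) - 1)) for (j in (i + 1):length(pos)) {
    d <- pos[j] - pos[i]
    r2 <- r2_pair(p$geno[, i], p$geno[, j])
    if (d <= cfg$ld_block_bp) near <- c(near, r2)
    else if (d > 5 * cfg$ld_block_bp) far <- c(far, r2)
  }
  expect_gt(mean(near), mean(far))
  expect_gt(mean(near), 0.1)

  # independence limit: ld_block_bp = 0
  cfg0 <- small_cfg(n_lines = 120L, snps_per_arm = 120L, arms = "2L",
                    ld_block_bp = 0)
  p0 <- simulate_genotypes(cfg0)
  r2s <- sapply(seq_len(100), function(k) {
    ij <- sample.int(ncol(p0$geno), 2)
    r2_pair(p0$geno[, ij[1]], p0$geno[, ij[2]])
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("binned mean r2 declines monotonically over distance", {
  cfg <- small_cfg(n_lines = 150L, snps_per_arm = 150L, arms = "2L",
                   arm_length_bp = 30000L, seed = 4L)
  p <- simulate_genotypes(cfg)
  pos <- p$sites$pos
  d <- c(); r2 <- c()
  for (i in 1:(length(pos) - 1)) for (j in (i + 1):length(pos)) {
    dd <- pos[j] - pos[i]
    if (dd <= 2000) { d <- c(d, dd); r2 <- c(r2, r2_pair(p$geno[, i], p$geno[, j])) }
  }
  bins <- cut(d, c(0, 500, 1000, 2000))
  m <- tapply(r2, bins, mean)
  expect_true(all(diff(m) < 0))
})

test_that("realised MAF respects the target range and positions increase", {
  cfg <- small_cfg(target_maf_range = c(0.1, 0.4))
  p <- simulate_genotypes(cfg)
  maf <- panel_maf(p)
  n <- length(p$lines)
  expect_true(all(maf >= ceiling(0.1 * n) / n - 1e-9))
  expect_true(all(maf <= 0.4 + 1e-9))
  for (arm in unique(p$sites$arm))
    expect_false(is.unsorted(p$sites$pos[p$sites$arm == arm], strictly = TRUE))
})

test_that("fitness simulation hits the target G exactly and handles edges", {
  cfg <- small_cfg()
  p <- simulate_genotypes(cfg)
  f <- simulate_fitness(p, cfg)
  G_real <- cov(f$truth$line_values)
  expect_equal(G_real[1, 1], cfg$sigma2_Gm, tolerance = 1e-10)
  expect_equal(G_real[2, 2], cfg$sigma2_Gf, tolerance = 1e-10)
  expect_equal(G_real[1, 2], cfg$cov_Gmf, tolerance = 1e-10)

  # degenerate G: perfect cross-sex correlation
  s <- sqrt(0.1 * 0.2)
  cfgc <- small_cfg(sigma2_Gm = 0.1, sigma2_Gf = 0.2, cov_Gmf = s)
  fc <- simulate_fitness(p, cfgc)
  expect_equal(cor(fc$truth$line_values)[1, 2], 1, tolerance = 1e-8)

  # no causal sites: line-level genetic values are zero
  cfg0 <- small_cfg(n_antagonistic_causal = 0L, n_concordant_causal = 0L,
                    sigma2_Gm = 0, sigma2_Gf = 0, cov_Gmf = 0)
  f0 <- simulate_fitness(p, cfg0)
  expect_true(all(f0$truth$line_values == 0))

  expect_error(sim_config(sigma2_Gm = 0, cov_Gmf = 0.1), "covariance")
})

test_that("realised female heritability matches the plug-in formula target", {
  # sigma2_Gf = 0.27, sigma2_Rf = 1.0 -> h2f = 2*.27/1.27 = 0.425
  h2 <- replicate(20, {
    cfg <- small_cfg(n_lines = 150L, snps_per_arm = 40L,
                     sigma2_Gf = 0.27, sigma2_Rf = 1.0,
                     qc_fail_rate = 0, seed = sample.int(1e6, 1))
    p <- simulate_genotypes(cfg)
    f <- simulate_fitness(p, cfg)
    norm <- normalise_fitness(qc_vials(f$assays))
    fem <- norm[norm$sex == "F", ]
    anova_h2(fem$z, fem$line)
  })
  expect_lt(abs(mean(h2) - 0.42), 0.07)
})

test_that("comparison panels drift correctly and balancing elevates MAF", {
  cfg <- small_cfg()
  p <- simulate_genotypes(cfg)

  cfg0 <- small_cfg(drift_generations = 0L)
  c0 <- simulate_comparison_panel(p, cfg0)
  # zero generations: underlying frequencies equal the focal ones (the
  # haplotype sample adds only binomial noise around them)
  expect_lt(mean(abs(c0$freq - panel_alt_freq(p))),
            3 * sqrt(0.25 / cfg$n_comparison_haplotypes))

  bal <- seq_len(nrow(p$sites)) <= 30
  cb <- simulate_comparison_panel(p, small_cfg(drift_generations = 500L,
                                               balancing_strength = 0.05),
                                  balanced_truth = bal)
  maf <- pmin(cb$freq, 1 - cb$freq)
  expect_gt(mean(maf[bal]), mean(maf[!bal]))
  # strong drift fixes some neutral sites
  expect_gt(sum(maf[!bal] == 0), 0)
})

test_that("neutral Wright-Fisher drift conserves allele frequency in expectation", {
  cfg <- small_cfg(n_lines = 40L, snps_per_arm = 100L, arms = "2L",
                   balancing_strength = 0, drift_generations = 50L)
  p <- simulate_genotypes(cfg)
  p0 <- panel_alt_freq(p)
  drift_mean <- rowMeans(sapply(1:30, function(i) {
    cfg$seed <- i
    simulate_comparison_panel(p, cfg, seed_offset = 1000L + i)$freq
  }))
  expect_lt(mean(drift_mean - p0), 0.02)
  expect_lt(abs(mean(drift_mean) - mean(p0)), 0.01)
})

test_that("annotation generator honours category proportions", {
  cfg <- small_cfg()
  p <- simulate_genotypes(cfg)
  a_int <- simulate_annotations(p, cfg, category_probs = c(intergenic = 1))
  expect_true(all(a_int$site_category == "intergenic"))

  # binomial oracle: 10% missense over 10,000 sites within the 99% interval
  big <- toy_panel(4, 10000, seed = 2, pos = seq_len(10000) * 5L)
  cfg_big <- small_cfg(n_lines = 4L, snps_per_arm = 10000L, arms = "2L",
                       arm_length_bp = 100000L)
  ab <- simulate_annotations(big, cfg_big,
                             category_probs = c(missense = 0.1,
                                                intergenic = 0.9))
  obs <- sum(ab$site_category == "missense")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])

  expect_error(simulate_annotations(p, cfg,
                                    category_probs = c(missense = 0.5)),
               "sum to 1")
})
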