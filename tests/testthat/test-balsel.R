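test_that("residualize matches closed-form OLS", {
  set.seed(90)
  v <- rnorm(50)
  cov_orth <- rep(0, 50)                    # constant covariate: centring only
  expect_equal(residualize(v, cov_orth), v - mean(v), tolerance = 1e-12)
  expect_equal(residualize(v, v), rep(0, 50), tolerance = 1e-10)
  # 5-point closed form
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2.5, 3.7, 4.1, 5.2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(residualize(y, x), y - (a + b * x), tolerance = 1e-12)
})

test_that("matched null sets reproduce the candidates' bin histogram", {
  set.seed(91)
  m <- 2000
  lhm_maf <- runif(m, 0.05, 0.5)
  lsel <- runif(m)
  cand <- seq_len(m) %in% sample.int(m, 100)
  # instrument: the comparison value IS the residual-MAF bin id, so every
  # matched null mean must equal the candidates' mean bin id exactly
  resid_maf <- residualize(lhm_maf, lsel)
  br <- unique(quantile(resid_maf, seq(0, 1, length.out = 21)))
  bins <- cut(resid_maf, br, include.lowest = TRUE, labels = FALSE)
  r <- analysis_A_matched_null(cand, lhm_maf, lsel, as.numeric(bins),
                               n_sets = 50, seed = 7)
  expect_true(all(abs(r$null - mean(bins[cand])) < 1e-12))
})

test_that("matched null p-value has the right formula and error branch", {
  set.seed(92)
  m <- 1000
  lhm_maf <- runif(m, 0.05, 0.5)
  lsel <- runif(m)
  cand <- seq_len(m) %in% sample.int(m, 50)
  comp <- runif(m, 0, 0.5)
  comp[cand] <- comp[cand] + 10             # observed above every null
  r <- analysis_A_matched_null(cand, lhm_maf, lsel, comp, n_sets = 200,
                               seed = 8)
  expect_equal(r$p, 1 / 201)

  # control deficit: all high-residual-MAF sites are candidates
  lhm2 <- c(runif(950, 0.05, 0.3), runif(50, 0.45, 0.5))
  cand2 <- c(rep(FALSE, 950), rep(TRUE, 50))
  expect_error(analysis_A_matched_null(cand2, lhm2, runif(1000), comp,
                                       n_sets = 10),
               "bin")
})

test_that("matched null is calibrated when candidates are unremarkable", {
  ps <- replicate(40, {
    m <- 600
    lhm_maf <- runif(m, 0.05, 0.5)
    lsel <- runif(m)
    comp <- pmin(lhm_maf + rnorm(m, 0, 0.05), 0.5)   # null: no enrichment
    cand <- seq_len(m) %in% sample.int(m, 40)
    analysis_A_matched_null(cand, lhm_maf, lsel, comp, n_sets = 100,
                            seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("persistence logit recovers a known slope and flags separation", {
  set.seed(93)
  n <- 5000
  beta <- abs(rnorm(n))
  maf <- runif(n, 0.05, 0.5)
  lsel <- runif(n)
  eta <- -0.5 + 1.0 * beta                  # true log-odds slope 1.0
  flag <- runif(n) < plogis(eta)
  r <- analysis_B_persistence_logit(flag, beta, maf, lsel)
  expect_lt(abs(log(r$or_per_unit) - 1.0), 0.15)
  expect_lt(r$p, 1e-6)
  expect_false(r$separation)

  r2 <- analysis_B_persistence_logit(rep(TRUE, 100), runif(100),
                                     runif(100), runif(100))
  expect_true(r2$separation)
  expect_true(is.na(r2$or_per_unit))
})

test_that("binned Spearman draws one site per bin and ranks correctly", {
  # exact full grid: 20 x 100 cells, one point each -> 2000 drawn
  grid <- expand.grid(mafq = seq_len(20), betaq = seq_len(100))
  resid_maf <- grid$mafq + runif(2000, 0, 0.5)
  abs_beta <- grid$betaq + runif(2000, 0, 0.5)
  comp_maf <- abs_beta + rnorm(2000, 0, 1e-6)   # monotone in effect size
  r <- analysis_C_binned_spearman(comp_maf, abs_beta, resid_maf, seed = 9)
  expect_equal(r$n_drawn, 2000L)
  expect_equal(r$rho, 1, tolerance = 1e-9)

  set.seed(94)
  r0 <- analysis_C_binned_spearman(runif(2000), abs_beta, resid_maf,
                                   seed = 10)
  expect_lt(abs(r0$rho), 0.1)
})

test_that("trans-specific flags require shared polymorphism and alleles", {
  p <- toy_panel(20, 3, seed = 95)
  comp <- list(
    freq = c(0.5, 0, 0.3),
    sites = data.frame(comp_ref = c("A", "A", "T"),
                       comp_alt = c("T", "T", "C")))
  # site 1: polymorphic, same pair -> TRUE
  # site 2: monomorphic in species -> FALSE
  # site 3: polymorphic but different alleles -> FALSE
  flags <- trans_specific_flags(p, comp)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
  # allele order does not matter
  comp$sites$comp_ref[1] <- "T"; comp$sites$comp_alt[1] <- "A"
  expect_true(trans_specific_flags(p, comp)[1])
})

test_that("comparison MAF applies the allele-matching zero rule", {
  cfg <- small_cfg(seed = 96L)
  p <- simulate_genotypes(cfg)
  comp <- simulate_comparison_panel(p, cfg)
  cm <- comparison_maf(p, comp)
  expect_true(all(cm >= 0 & cm <= 0.5))
  expect_true(all(cm[comp$freq %in% c(0, 1)] == 0))
  mismatch <- comp$sites$comp_alt != p$sites$alt
  expect_true(all(cm[mismatch] == 0))
})
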