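test_that("window diversity matches a from-scratch Tajima oracle", {
  # printed toy alignment: 4 haplotypes, 3 segregating sites in one window
  H <- rbind(c(0L, 0L, 1L),
             c(0L, 1L, 1L),
             c(1L, 0L, 0L),
             c(0L, 0L, 1L))
  sites <- data.frame(arm = "2L", pos = c(101L, 205L, 377L))
  wd <- window_diversity(H, sites, window = 1000L, step = 1000L)
  w1 <- wd[wd$start == 0, ]
  expect_equal(w1$S, 3L)
  expect_equal(w1$tajima_d, oracle_tajima_d(H), tolerance = 1e-12)

  # 200 random small alignments against the oracle
  set.seed(100)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    m <- sample(2:8, 1)
    Hr <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    sr <- data.frame(arm = "2L", pos = sort(sample.int(900, m)))
    d_pkg <- window_diversity(Hr, sr, window = 1000L, step = 1000L)$tajima_d[1]
    d_orc <- oracle_tajima_d(Hr)
    if (is.na(d_orc)) expect_true(is.na(d_pkg))
    else expect_equal(d_pkg, d_orc, tolerance = 1e-10)
  }
})

test_that("Tajima's D has the right sign for skewed frequency spectra", {
  n <- 20
  # all singletons -> negative D
  Hs <- matrix(0L, n, 10)
  for (j in 1:10) Hs[j, j] <- 1L
  ss <- data.frame(arm = "2L", pos = seq(10L, 100L, by = 10L))
  expect_lt(window_diversity(Hs, ss, 1000L, 1000L)$tajima_d[1], 0)
  # all intermediate-frequency -> positive D
  Hi <- matrix(rep(rep(c(0L, 1L), each = n / 2), 10), n, 10)
  expect_gt(window_diversity(Hi, ss, 1000L, 1000L)$tajima_d[1], 0)
  # S = 0 -> undefined
  H0 <- matrix(0L, 5, 3)
  s0 <- data.frame(arm = "2L", pos = c(10L, 20L, 30L))
  expect_true(is.na(window_diversity(H0, s0, 1000L, 1000L)$tajima_d[1]))
  expect_error(window_diversity(H0[1:3, ], s0), "4 haplotypes")
})

test_that("Hudson F_ST matches the per-site oracle and its bounds", {
  expect_equal(hudson_fst(c(0.3, 0.4), c(0.3, 0.4), 50, 50), 0,
               tolerance = 0.05)
  expect_gt(hudson_fst(1, 0, 10000, 10000), 0.999)

  # toy two-site window vs independent per-site oracle
  o1 <- oracle_hudson_site(0.2, 0.8, 50, 50)
  o2 <- oracle_hudson_site(0.8, 0.2, 50, 50)
  expect_equal(hudson_fst(c(0.2, 0.8), c(0.8, 0.2), 50, 50),
               (o1["num"] + o2["num"]) / (o1["den"] + o2["den"]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # 100 random instances: aggregation never exceeds the max per-site ratio
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    p1 <- runif(k, 0.05, 0.95); p2 <- runif(k, 0.05, 0.95)
    agg <- hudson_fst(p1, p2, 40, 60)
    per_site <- sapply(seq_len(k), function(j) {
      o <- oracle_hudson_site(p1[j], p2[j], 40, 60)
      o["num"] / o["den"]
    })
    expect_lte(agg, max(per_site) + 1e-10)
    expect_equal(hudson_fst(p1, p2, 40, 60),
                 sum(sapply(seq_len(k), function(j)
                   oracle_hudson_site(p1[j], p2[j], 40, 60)["num"])) /
                   sum(sapply(seq_len(k), function(j)
                     oracle_hudson_site(p1[j], p2[j], 40, 60)["den"])),
                 tolerance = 1e-10)
  }
})

test_that("residual Tajima's D regression detects elevated windows", {
  set.seed(102)
  n <- 300
  lsel <- runif(n)
  flag <- rep(c(TRUE, FALSE), c(60, 240))
  d <- 0.5 * lsel + ifelse(flag, 0.8, 0) + rnorm(n, 0, 0.3)
  r <- window_diversity_test(d, flag, lsel)
  expect_gt(r$coef, 0.5)
  expect_lt(r$p, 1e-6)
  expect_error(window_diversity_test(d, rep(TRUE, n), lsel), "both window")

  # random flags: no signal
  r0 <- window_diversity_test(rnorm(n), sample(flag), lsel)
  expect_gt(r0$p, 0.001)
})

test_that("LD class comparison fits decay and flags sparse classes", {
  cfg <- small_cfg(n_lines = 80L, snps_per_arm = 150L, arms = "2L",
                   arm_length_bp = 30000L, seed = 103L)
  p <- simulate_genotypes(cfg)
  H <- p$geno
  set.seed(104)
  cand <- seq_len(ncol(H)) %in% sample.int(ncol(H), 40)
  r <- ld_class_comparison(H, p$sites, cand, max_dist = 2000)
  expect_true(all(r$pairs$dist > 0))          # d = 0 self-pairs excluded
  expect_true(all(c("a", "b", "c") %in% names(r$fit)))
  expect_gt(r$fit["b"], 0)                    # decay scale positive
  # random labels: residual differences not significant at alpha = 1e-4
  expect_gt(min(unlist(r$tests), na.rm = TRUE), 1e-4)

  # only 2 candidates -> candidate class flagged sparse
  cand2 <- seq_len(ncol(H)) %in% c(1L, 2L)
  r2 <- ld_class_comparison(H, p$sites, cand2, max_dist = 2000)
  expect_true("candidate" %in% r2$flagged_classes)
})

test_that("elevated candidate LD is detected on planted haplotypes", {
  # candidates sit on a long shared haplotype; controls are independent
  set.seed(105)
  n <- 100
  hap <- rbinom(n, 1, 0.5)
  m <- 40
  G <- matrix(rbinom(n * m, 1, 0.4), n, m)
  cand_idx <- 1:10
  for (j in cand_idx) {
    flip <- rbinom(n, 1, 0.05)
    G[, j] <- ifelse(flip == 1, 1L - hap, hap)
  }
  pos <- sort(sample.int(3000, m))
  sites <- data.frame(arm = "2L", pos = pos)
  cand <- seq_len(m) %in% cand_idx
  r <- ld_class_comparison(G, sites, cand, max_dist = 3000)
  med <- tapply(r$pairs$resid, r$pairs$class, median)
  expect_gt(med["candidate"], med["control"])
  expect_lt(r$tests$candidate_vs_control, 0.01)
})

test_that("window F_ST contrast runs end to end on simulated panels", {
  cfg <- small_cfg(n_lines = 60L, snps_per_arm = 120L, arms = "2L",
                   arm_length_bp = 20000L, seed = 106L,
                   drift_generations = 100L)
  p <- simulate_genotypes(cfg)
  bal <- seq_len(nrow(p$sites)) <= 30
  c1 <- simulate_comparison_panel(p, cfg, bal, seed_offset = 5L)
  c2 <- simulate_comparison_panel(p, cfg, bal, seed_offset = 6L)
  wins <- tile_windows(p$sites)
  set.seed(107)
  antag <- runif(nrow(wins)) < 0.3
  lsel <- runif(nrow(wins))
  r <- window_fst_test(c1, c2, p$sites, antag, lsel)
  expect_true(all(r$fst[!is.na(r$fst)] <= 1 + 1e-9))
  expect_true(r$p > 0 && r$p <= 1)
})
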