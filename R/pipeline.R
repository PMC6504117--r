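#' Pipeline configuration with standard defaults
#'
#' Collects every stage threshold with defaults fixed at the reference
#' analysis values: call filters DP >= 10 / GQ >= 30, individual
#' missingness 15\%, call rate 95\%, MAF > 0.05, LD pruning r2 > 0.2 in
#' 10 kb, MAF exponent alpha = -0.25, candidate SNPs at Q < 0.3, windows
#' 1,000 bp / 500 bp step with Q < 0.1, clumping p <= 0.00093 / r2 > 0.4 /
#' 10 kb.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param out_dir output directory for tables, JSON and the manifest.
#' @param seed master seed (propagated to every stochastic stage).
#' @param min_depth,min_gq,max_missing,min_call_rate,min_maf QC thresholds.
#' @param alpha MAF exponent for kinships.
#' @param q_snp,q_window candidate cutoffs.
#' @param clump_p,clump_r2,clump_dist clumping parameters.
#' @param window,step window geometry (bp).
#' @param n_perm_h2,n_perm_gwas,n_perm_cluster,n_sets_matched permutation
#'   budgets.
#' @param gibbs_iter,gibbs_burn,gibbs_thin chain settings for the
#'   G-matrix fit.
#' @param stages character vector of stages to run (subset of simulate,
#'   qc, fitness, quantgen, gwas, windows, clump, partition, genes,
#'   balsel).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = tempfile("antagwas_"),
                            seed = 42L,
                            min_depth = 10, min_gq = 30, max_missing = 0.15,
                            min_call_rate = 0.95, min_maf = 0.05,
                            alpha = -0.25, q_snp = 0.3, q_window = 0.1,
                            clump_p = 0.00093, clump_r2 = 0.4,
                            clump_dist = 10000,
                            window = 1000L, step = 500L,
                            n_perm_h2 = 100L, n_perm_gwas = 200L,
                            n_perm_cluster = 200L, n_sets_matched = 200L,
                            gibbs_iter = 4000L, gibbs_burn = 1000L,
                            gibbs_thin = 5L,
                            stages = c("simulate", "qc", "fitness",
                                       "quantgen", "gwas", "windows",
                                       "clump", "partition", "genes",
                                       "balsel")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> genotype QC -> fitness QC -> G-matrix ->
#' GWAS (+ empirical p) -> windows -> clumping/clustering -> partition ->
#' gene analyses -> balancing-selection tests, as toggled in the config,
#' writing TSV/JSON outputs and a reproducibility manifest (package
#' version, seed, config echo, output MD5 hashes) to `config$out_dir`.
#' Reruns with the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  stage_on <- function(s) s %in% config$stages

  sim <- config$sim
  sim$seed <- config$seed

  ## --- simulate -----------------------------------------------------
  panel <- simulate_genotypes(sim)
  # per-call depth/quality with a small low-quality tail so the call
  # filter has work to do
  set.seed(config$seed + 11L)
  n <- length(panel$lines); m <- nrow(panel$sites)
  panel$dp <- matrix(stats::rpois(n * m, 30), n, m)
  panel$gq <- matrix(pmin(99L, stats::rpois(n * m, 70)), n, m)
  low <- stats::runif(n * m) < 0.01
  panel$dp[low] <- sample(0:9, sum(low), replace = TRUE)
  vcf_path <- file.path(config$out_dir, "panel.vcf")
  if (stage_on("simulate")) {
    write_panel_vcf(panel, vcf_path)
    report$stages$simulate <- list(lines = n, sites = m,
                                   vcf = basename(vcf_path))
  }

  ## --- genotype QC --------------------------------------------------
  qc <- filter_calls(panel, config$min_depth, config$min_gq)
  qc <- filter_individuals(qc, config$max_missing)
  fs <- filter_sites(qc, config$min_call_rate, config$min_maf)
  qc <- fs$panel
  pruned_idx <- ld_prune(qc, r2_max = 0.2, window_bp = 10000)
  pc <- pca_outliers(subset_sites(qc, pruned_idx))
  if (any(pc$outlier)) {
    keep <- !pc$outlier
    qc <- new_genotype_panel(qc$lines[keep], qc$sites,
                             qc$geno[keep, , drop = FALSE])
  }
  if (stage_on("qc")) {
    rep_path <- file.path(config$out_dir, "qc_report.json")
    jsonlite::write_json(list(funnel = unclass(fs$report),
                              individuals = length(qc$lines),
                              pca_outliers = sum(pc$outlier),
                              ld_pruned_sites = length(pruned_idx)),
                         rep_path, auto_unbox = TRUE, digits = NA)
    report$stages$qc <- list(final_sites = ncol(qc$geno),
                             final_individuals = length(qc$lines),
                             pca_outliers = sum(pc$outlier))
  }

  ## --- fitness ------------------------------------------------------
  fsim <- simulate_fitness(panel, sim)
  assays <- fsim$assays
  norm <- normalise_fitness(qc_vials(assays))
  lf <- rotate_indices(line_means(norm))
  lf <- lf[lf$complete & lf$line %in% qc$lines, , drop = FALSE]
  qc <- new_genotype_panel(lf$line, qc$sites,
                           qc$geno[match(lf$line, qc$lines), , drop = FALSE])
  if (stage_on("fitness")) {
    write_tsv(assays, file.path(config$out_dir, "assays.tsv"))
    write_tsv(lf, file.path(config$out_dir, "line_fitness.tsv"))
    report$stages$fitness <- list(lines = nrow(lf))
  }

  ## --- quantgen -----------------------------------------------------
  if (stage_on("quantgen")) {
    fitg <- suppressWarnings(fit_bivariate_model(
      norm[norm$line %in% lf$line, ],
      n_iter = config$gibbs_iter, burn = config$gibbs_burn,
      thin = config$gibbs_thin, seed = config$seed + 21L))
    est <- as.list(fitg$estimate)
    est$hpd <- apply(fitg$hpd, 1L, identity, simplify = FALSE)
    jsonlite::write_json(est, file.path(config$out_dir, "gmatrix.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$quantgen <- fitg$estimate[c("h2_m", "h2_f", "r_mf")]
  }

  ## --- association --------------------------------------------------
  y <- lf$antagonism_index
  w <- ld_weights(qc)
  km <- kinship(qc, weights = w, alpha = config$alpha)
  fit <- gwas_lmm(y, qc, km)
  res <- fit$result
  res$q <- bh_qvalues(res$p)
  res$candidate <- !is.na(res$q) & res$q < config$q_snp
  lambda <- inflation_factor(res$p)
  if (stage_on("gwas")) {
    res$p_emp <- whitening_permutation(fit, qc, n_perm = config$n_perm_gwas,
                                       seed = config$seed + 31L)
    write_tsv(res, file.path(config$out_dir, "assoc.tsv"))
    report$stages$gwas <- list(n_snps = sum(!is.na(res$p)),
                               h2_snp = fit$h2_snp, lambda = lambda,
                               n_candidates = sum(res$candidate))
  }

  ## --- windows ------------------------------------------------------
  wres <- NULL
  if (stage_on("windows")) {
    wres <- window_set_test(y, qc, window = config$window,
                            step = config$step, alpha = config$alpha,
                            q_threshold = config$q_window)
    write_tsv(wres, file.path(config$out_dir, "windows.tsv"))
    report$stages$windows <- list(n_windows = sum(!is.na(wres$p)),
                                  n_antagonistic = sum(wres$antagonistic))
  }

  ## --- clump + clustering -------------------------------------------
  cl <- NULL
  if (stage_on("clump")) {
    cl <- clump(res, qc, p_index_max = config$clump_p,
                r2_min = config$clump_r2, dist_bp = config$clump_dist)
    ct <- cluster_permutation_test(qc$sites, res$candidate,
                                   n_perm = config$n_perm_cluster,
                                   seed = config$seed + 41L)
    write_tsv(data.frame(site = seq_along(cl$cluster),
                         cluster = cl$cluster),
              file.path(config$out_dir, "clusters.tsv"))
    report$stages$clump <- list(n_clusters = cl$n_clusters,
                                clustering = ct)
  }

  ## --- annotations, partition, genes --------------------------------
  ann <- simulate_annotations(panel, sim)
  ann_idx <- match(paste0(qc$sites$arm, ":", qc$sites$pos),
                   paste0(panel$sites$arm, ":", panel$sites$pos))
  cats <- as.character(ann$site_category)[ann_idx]
  if (stage_on("partition")) {
    compartment <- ifelse(qc$sites$arm == "X", "X", "autosome")
    part <- partition_h2(y, qc, compartment, weights = w,
                         alpha = config$alpha)
    enr <- category_enrichment_z(res$candidate, compartment == "X")
    jsonlite::write_json(list(partition = part, x_enrichment = enr),
                         file.path(config$out_dir, "partition.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$stages$partition <- list(shares = stats::setNames(part$share,
                                                             part$class))
  }
  if (stage_on("genes")) {
    gt <- build_gene_table(ann, qc$sites, res$candidate)
    out <- list(n_antagonistic_genes = sum(gt$antagonistic))
    if (sum(gt$antagonistic) >= 3L) {
      out$sexbias_class <- sexbias_class_test(gt)
      out$sexbias_quant <- sexbias_quantitative(gt)
      gtt <- gt[!gt$sex_limited & !is.na(gt$tau), ]
      out$tau_wilcox_p <- if (length(unique(gtt$antagonistic)) == 2L)
        stats::wilcox.test(gtt$tau[gtt$antagonistic],
                           gtt$tau[!gtt$antagonistic])$p.value else NA
      out$ppi <- ppi_glm(gt$ppi, gt$antagonistic)
    }
    write_tsv(gt, file.path(config$out_dir, "genes.tsv"))
    report$stages$genes <- out["n_antagonistic_genes"]
  }

  ## --- balancing selection ------------------------------------------
  if (stage_on("balsel")) {
    truth_balanced <- rep(FALSE, nrow(panel$sites))
    ants <- fsim$truth$causal$site[fsim$truth$causal$type == "antagonistic"]
    if (length(ants)) {
      set.seed(config$seed + 51L)
      nb <- max(1L, round(sim$balanced_fraction * length(ants)))
      truth_balanced[sample(ants, nb)] <- TRUE
    }
    comp <- simulate_comparison_panel(panel, sim, truth_balanced,
                                      label = "compA", seed_offset = 52L)
    cmaf_all <- comparison_maf(panel, comp)
    cmaf <- cmaf_all[ann_idx]
    lsel <- site_linked_sel(qc$sites, ann$linked_sel)
    lhm_maf <- panel_maf(qc)
    bal <- list()
    cand_pruned <- if (!is.null(cl)) seq_len(nrow(res)) %in% cl$index
                   else res$candidate
    if (sum(cand_pruned) >= 5L) {
      bal$analysis_A <- tryCatch(
        unclass(analysis_A_matched_null(cand_pruned, lhm_maf, lsel, cmaf,
                                        n_sets = config$n_sets_matched,
                                        seed = config$seed + 53L))[
                                          c("observed", "p", "naive_null_mean")],
        error = function(e) list(error = conditionMessage(e)))
    }
    poly <- cmaf > 0
    bal$analysis_B <- analysis_B_persistence_logit(poly, abs(res$beta),
                                                   lhm_maf, lsel)
    bal$analysis_C <- analysis_C_binned_spearman(
      cmaf, abs(res$beta), residualize(lhm_maf, lsel),
      maf_bins = 20L, beta_bins = 100L, seed = config$seed + 54L)
    if (!is.null(wres)) {
      wd <- window_diversity(comp$haplotypes, panel$sites,
                             window = config$window, step = config$step)
      wl <- site_linked_sel(
        data.frame(arm = wd$arm, pos = wd$start + 1L), ann$linked_sel)
      ok <- !is.na(wd$tajima_d)
      if (length(unique(wres$antagonistic[ok])) == 2L)
        bal$tajima_test <- window_diversity_test(wd$tajima_d,
                                                 wres$antagonistic, wl)
      comp2 <- simulate_comparison_panel(panel, sim, truth_balanced,
                                         label = "compB", seed_offset = 62L)
      bal$fst_test <- tryCatch(
        window_fst_test(comp, comp2, panel$sites, wres$antagonistic, wl,
                        config$window, config$step)[c("W", "p", "median_diff")],
        error = function(e) list(error = conditionMessage(e)))
    }
    species <- simulate_comparison_panel(panel, sim, truth_balanced,
                                         label = "species",
                                         allele_switch_rate = 0.1,
                                         seed_offset = 72L)
    ts <- trans_specific_flags(panel, species)
    bal$trans_specific <- list(n_trans = sum(ts),
                               prop_candidates = mean(ts[ann_idx][res$candidate]),
                               prop_all = mean(ts[ann_idx]))
    jsonlite::write_json(bal, file.path(config$out_dir, "balsel.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    report$stages$balsel <- list(
      analysis_A_p = bal$analysis_A$p %||% NA,
      analysis_B_p = bal$analysis_B$p,
      analysis_C_rho = bal$analysis_C$rho)
  }

  ## --- manifest -----------------------------------------------------
  report$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json", "report.json")]
  manifest <- list(
    package = "antagwas",
    version = as.character(utils::packageVersion("antagwas")),
    seed = config$seed,
    config = config_echo(config),
    output_md5 = stats::setNames(as.list(tools::md5sum(sort(outputs))),
                                 basename(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$elapsed_s <- NULL   # keep report.json reproducible bit-for-bit
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# plain-list echo of the config for the manifest (drops the class)
config_echo <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$out_dir <- NULL
  out
}
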