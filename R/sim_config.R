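#' Simulation configuration for a synthetic hemiclone study
#'
#' Bundles every parameter of the synthetic-data generator: panel dimensions,
#' LD structure, the target cross-sex genetic (co)variance matrix on the
#' scaled-fitness scale, assay design, and the comparison-panel
#' drift/balancing settings.
#'
#' @param n_lines number of hemiclonal lines (haploid genomes).
#' @param snps_per_arm number of segregating sites per chromosome arm.
#' @param arms chromosome arm names; defaults to the five major
#'   \emph{D. melanogaster} arms.
#' @param arm_length_bp physical length of each simulated arm in bp.
#' @param ld_block_bp expected haplotype-block length (bp); the per-bp
#'   recombination probability of the haplotype-copying model is
#'   `1/ld_block_bp`. `0` gives fully independent sites.
#' @param n_founders number of founder haplotypes per arm for the
#'   copying model.
#' @param target_maf_range length-2 numeric in (0, 0.5]; realised minor
#'   allele frequencies are kept inside this range.
#' @param n_antagonistic_causal,n_concordant_causal numbers of causal sites
#'   with sex-opposed and sex-aligned fitness effects.
#' @param sigma2_Gm,sigma2_Gf,cov_Gmf genetic variances and cross-sex
#'   covariance of line-level fitness (scaled-fitness units).
#' @param sigma2_Rm,sigma2_Rf sex-specific residual variances.
#' @param n_blocks number of assay blocks.
#' @param flies_per_vial focal flies per competition vial.
#' @param vials_per_block vials per line/sex/block.
#' @param qc_fail_rate probability that a vial is injected with a QC failure
#'   (missing focal males, dead female, or <2 eggs).
#' @param balanced_fraction proportion of antagonistic causal sites put under
#'   balancing selection in comparison panels.
#' @param balancing_strength per-generation pull towards the balanced
#'   equilibrium frequency (`s` in `p <- p + s*(p_eq - p)`).
#' @param balancing_eq equilibrium frequency of balanced sites.
#' @param drift_generations Wright-Fisher generations separating a comparison
#'   panel from the focal population.
#' @param drift_N haploid population size used for the Wright-Fisher step.
#' @param n_comparison_haplotypes haplotypes sampled per comparison panel.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 200L,
                       snps_per_arm = 400L,
                       arms = c("2L", "2R", "3L", "3R", "X"),
                       arm_length_bp = 200000L,
                       ld_block_bp = 1000,
                       n_founders = 16L,
                       target_maf_range = c(0.05, 0.5),
                       n_antagonistic_causal = 40L,
                       n_concordant_causal = 40L,
                       sigma2_Gm = 0.0870,
                       sigma2_Gf = 0.2658,
                       cov_Gmf = 0.0228,
                       sigma2_Rm = 1.0,
                       sigma2_Rf = 1.0,
                       n_blocks = 5L,
                       flies_per_vial = 5L,
                       vials_per_block = 5L,
                       qc_fail_rate = 0.05,
                       balanced_fraction = 1.0,
                       balancing_strength = 0.05,
                       balancing_eq = 0.5,
                       drift_generations = 500L,
                       drift_N = 200L,
                       n_comparison_haplotypes = 100L,
                       seed = 42L) {
  cfg <- list(
    n_lines = as.integer(n_lines), snps_per_arm = as.integer(snps_per_arm),
    arms = as.character(arms), arm_length_bp = as.integer(arm_length_bp),
    ld_block_bp = as.numeric(ld_block_bp), n_founders = as.integer(n_founders),
    target_maf_range = as.numeric(target_maf_range),
    n_antagonistic_causal = as.integer(n_antagonistic_causal),
    n_concordant_causal = as.integer(n_concordant_causal),
    sigma2_Gm = sigma2_Gm, sigma2_Gf = sigma2_Gf, cov_Gmf = cov_Gmf,
    sigma2_Rm = sigma2_Rm, sigma2_Rf = sigma2_Rf,
    n_blocks = as.integer(n_blocks),
    flies_per_vial = as.integer(flies_per_vial),
    vials_per_block = as.integer(vials_per_block),
    qc_fail_rate = qc_fail_rate,
    balanced_fraction = balanced_fraction,
    balancing_strength = balancing_strength,
    balancing_eq = balancing_eq,
    drift_generations = as.integer(drift_generations),
    drift_N = as.integer(drift_N),
    n_comparison_haplotypes = as.integer(n_comparison_haplotypes),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_lines >= 1L, cfg$snps_per_arm >= 1L, length(cfg$arms) >= 1L,
    cfg$n_blocks >= 1L, cfg$flies_per_vial >= 1L, cfg$vials_per_block >= 1L,
    cfg$n_founders >= 2L, cfg$arm_length_bp >= cfg$snps_per_arm
  )
  r <- cfg$target_maf_range
  if (length(r) != 2L || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    stop("target_maf_range must satisfy 0 < min <= max <= 0.5")
  G <- matrix(c(cfg$sigma2_Gm, cfg$cov_Gmf, cfg$cov_Gmf, cfg$sigma2_Gf), 2L)
  if (any(c(cfg$sigma2_Gm, cfg$sigma2_Gf, cfg$sigma2_Rm, cfg$sigma2_Rf) < 0))
    stop("variances must be non-negative")
  if ((cfg$sigma2_Gm == 0 || cfg$sigma2_Gf == 0) && cfg$cov_Gmf != 0)
    stop("a zero genetic variance with nonzero cross-sex covariance is not a valid G matrix")
  if (det(G) < -1e-12 * max(1, cfg$sigma2_Gm * cfg$sigma2_Gf))
    stop("G matrix [[sigma2_Gm, cov],[cov, sigma2_Gf]] is not positive semi-definite")
  if (cfg$drift_generations < 0L) stop("drift_generations must be >= 0")
  if (cfg$qc_fail_rate < 0 || cfg$qc_fail_rate > 1)
    stop("qc_fail_rate must be in [0,1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic hemiclone study configuration\n")
  cat(sprintf("  lines: %d, arms: %s (%d SNPs each)\n",
              x$n_lines, paste(x$arms, collapse = ","), x$snps_per_arm))
  cat(sprintf("  LD block %.0f bp; MAF in [%.2f, %.2f]\n",
              x$ld_block_bp, x$target_maf_range[1], x$target_maf_range[2]))
  cat(sprintf("  G = [[%.4f, %.4f], [%.4f, %.4f]]; residuals (%.2f, %.2f)\n",
              x$sigma2_Gm, x$cov_Gmf, x$cov_Gmf, x$sigma2_Gf,
              x$sigma2_Rm, x$sigma2_Rf))
  cat(sprintf("  causal sites: %d antagonistic + %d concordant; seed %d\n",
              x$n_antagonistic_causal, x$n_concordant_causal, x$seed))
  invisible(x)
}
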