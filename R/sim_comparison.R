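#' Simulate a comparison population panel by Wright-Fisher drift
#'
#' Starting from the focal panel's alternate-allele frequencies, each site
#' evolves for `drift_generations` generations of binomial Wright-Fisher
#' drift in a haploid population of size `drift_N`. Sites flagged as
#' balanced are pulled deterministically towards the equilibrium frequency
#' before each binomial draw (`p <- p + s * (p_eq - p)`), emulating
#' balancing selection of strength `s`; with `s = 0` they are
#' indistinguishable from neutral sites. Some neutral sites fix (MAF 0). A
#' haplotype sample is then drawn site-independently from the final
#' frequencies so window statistics (pi, Watterson's theta, Tajima's D,
#' F_ST) can be computed. A small fraction of sites that fixed can acquire
#' a different alternate allele, emulating independent mutation in the
#' comparison lineage (relevant to trans-specific polymorphism calls).
#'
#' @param panel focal `genotype_panel`.
#' @param config [sim_config()]; uses `drift_generations`, `drift_N`,
#'   `balancing_strength`, `balancing_eq`, `n_comparison_haplotypes`.
#' @param balanced_truth logical per site: under balancing selection.
#' @param label population label (e.g. "DGRP", "ZI", "SA", "sim").
#' @param allele_switch_rate probability that a site fixed in the comparison
#'   population re-mutates to a different alternate allele.
#' @param seed_offset integer added to `config$seed` so several panels from
#'   one config are independent but reproducible.
#' @return A `comparison_panel`: list with `label`, `sites` (focal site
#'   table plus comparison `ref`/`alt`), `freq` (final alternate-allele
#'   frequency), `call_n`, `haplotypes` (n_hap x sites 0/1 matrix),
#'   `balanced_truth`.
#' @export
simulate_comparison_panel <- function(panel, config, balanced_truth = NULL,
                                      label = "sim", allele_switch_rate = 0.02,
                                      seed_offset = 2L) {
  validate_sim_config(config)
  m <- nrow(panel$sites)
  if (is.null(balanced_truth)) balanced_truth <- rep(FALSE, m)
  stopifnot(length(balanced_truth) == m)
  set.seed(config$seed + seed_offset)

  p <- panel_alt_freq(panel)
  s <- config$balancing_strength
  peq <- config$balancing_eq
  N <- config$drift_N
  for (g in seq_len(config$drift_generations)) {
    p[balanced_truth] <- p[balanced_truth] + s * (peq - p[balanced_truth])
    p <- stats::rbinom(m, N, p) / N
  }

  n_hap <- config$n_comparison_haplotypes
  H <- matrix(stats::rbinom(n_hap * m, 1L, rep(p, each = n_hap)), n_hap, m)
  colnames(H) <- colnames(panel$geno)

  sites <- panel$sites
  sites$comp_ref <- sites$ref
  sites$comp_alt <- sites$alt
  fixed <- which(p %in% c(0, 1) & !balanced_truth)
  if (length(fixed)) {
    switch_idx <- fixed[stats::runif(length(fixed)) < allele_switch_rate]
    bases <- c("A", "C", "G", "T")
    for (j in switch_idx) {
      sites$comp_alt[j] <- sample(setdiff(bases, c(sites$ref[j], sites$alt[j])), 1L)
      # the new mutation segregates at low frequency
      k <- max(1L, stats::rbinom(1L, n_hap, 0.05))
      H[, j] <- 0L
      H[sample.int(n_hap, k), j] <- 1L
    }
  }

  structure(list(label = label, sites = sites,
                 freq = colMeans(H), call_n = rep(n_hap, m),
                 haplotypes = H, balanced_truth = balanced_truth),
            class = "comparison_panel")
}

#' @export
print.comparison_panel <- function(x, ...) {
  cat(sprintf("Comparison panel '%s': %d haplotypes x %d sites; %d balanced-truth sites\n",
              x$label, nrow(x$haplotypes), ncol(x$haplotypes),
              sum(x$balanced_truth)))
  invisible(x)
}

#' Comparison-population MAF under the allele-matching rule
#'
#' A focal site's MAF in a comparison panel is the minor-allele frequency
#' there, but set to 0 when the site is monomorphic in the comparison
#' population or when the segregating alleles do not match the focal pair.
#'
#' @param panel focal `genotype_panel` (provides the focal allele pair).
#' @param comp a `comparison_panel`.
#' @return numeric vector in `[0, 0.5]`.
#' @export
comparison_maf <- function(panel, comp) {
  maf <- pmin(comp$freq, 1 - comp$freq)
  mismatch <- comp$sites$comp_ref != panel$sites$ref |
    comp$sites$comp_alt != panel$sites$alt
  maf[comp$freq %in% c(0, 1) | mismatch] <- 0
  maf
}
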