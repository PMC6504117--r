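#' Residuals of a simple linear regression
#'
#' Removes the linear effect of a covariate (typically linked selection)
#' from a quantity before between-class comparisons. Residuals have mean
#' zero; observations with a missing covariate get NA.
#'
#' @param values numeric response.
#' @param covariate numeric covariate, same length.
#' @return numeric residuals.
#' @export
residualize <- function(values, covariate) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & !is.na(covariate)
  fit <- stats::lm(values[ok] ~ covariate[ok])
  out[ok] <- stats::resid(fit)
  out
}

#' Matched Monte-Carlo null for comparison-population polymorphism
#'
#' Tests whether candidate (antagonistic) sites carry more polymorphism in
#' an independent population than matched control sites. Focal-population
#' MAF is first residualised on linked selection; controls are then
#' stratified into `n_bins` quantile bins of the residual MAF, and each of
#' `n_sets` null sets draws (without replacement, within a set) exactly
#' the candidates' bin counts — so every null set reproduces the
#' candidates' residual-MAF histogram. The statistic is the mean
#' comparison-population value (MAF under the allele-matching rule, or a
#' trans-specific proportion) and the one-sided empirical p-value is
#' \eqn{(1 + \#\{null \ge obs\}) / (1 + n_{sets})}.
#'
#' @param candidate logical per site (LD-pruned upstream).
#' @param lhm_maf focal-population MAF per site.
#' @param linked_sel linked-selection value per site.
#' @param comp_value comparison-population quantity per site (MAF or 0/1
#'   trans-specific flag).
#' @param n_sets number of null sets (default 1000).
#' @param n_bins residual-MAF quantile bins (default 20).
#' @param seed RNG seed.
#' @param alternative "greater" (default, elevated polymorphism) or
#'   "two.sided".
#' @return `matched_null_result`: `observed`, `null` (vector of n_sets
#'   means), `p`, `naive_null_mean`, `n_candidates`, `bins` used.
#' @export
analysis_A_matched_null <- function(candidate, lhm_maf, linked_sel,
                                    comp_value, n_sets = 1000L, n_bins = 20L,
                                    seed = 1L, alternative = "greater") {
  stopifnot(length(candidate) == length(lhm_maf),
            length(lhm_maf) == length(comp_value))
  resid_maf <- residualize(lhm_maf, linked_sel)
  br <- unique(stats::quantile(resid_maf, seq(0, 1, length.out = n_bins + 1L),
                               na.rm = TRUE))
  bin <- cut(resid_maf, br, include.lowest = TRUE, labels = FALSE)
  cand_idx <- which(candidate)
  ctrl_idx <- which(!candidate)
  need <- table(factor(bin[cand_idx], levels = seq_along(br[-1])))
  avail <- table(factor(bin[ctrl_idx], levels = seq_along(br[-1])))
  short <- which(need > 0 & avail < need)
  if (length(short))
    stop("control deficit in residual-MAF bin(s): ",
         paste(short, collapse = ", "),
         " (candidates present but too few controls to match)")

  ctrl_by_bin <- split(ctrl_idx, factor(bin[ctrl_idx], levels = seq_along(br[-1])))
  set.seed(seed)
  null_means <- vapply(seq_len(n_sets), function(s) {
    drawn <- unlist(lapply(which(need > 0), function(b) {
      pool <- ctrl_by_bin[[b]]
      pool[sample.int(length(pool), need[b])]
    }), use.names = FALSE)
    mean(comp_value[drawn])
  }, numeric(1))

  obs <- mean(comp_value[cand_idx])
  p <- switch(alternative,
              greater = (1 + sum(null_means >= obs)) / (1 + n_sets),
              two.sided = {
                centre <- stats::median(null_means)
                (1 + sum(abs(null_means - centre) >= abs(obs - centre))) /
                  (1 + n_sets)
              },
              stop("alternative must be 'greater' or 'two.sided'"))
  structure(list(observed = obs, null = null_means, p = p,
                 naive_null_mean = mean(comp_value[ctrl_idx]),
                 n_candidates = length(cand_idx), bins = br),
            class = "matched_null_result")
}

#' @export
print.matched_null_result <- function(x, ...) {
  cat(sprintf("Matched Monte-Carlo null (%d candidates, %d sets)\n",
              x$n_candidates, length(x$null)))
  cat(sprintf("  observed mean %.4f vs matched null %.4f (naive %.4f); p = %.4g\n",
              x$observed, mean(x$null), x$naive_null_mean, x$p))
  invisible(x)
}

#' Polymorphism-persistence logistic regression
#'
#' Models whether a focal-population SNP remains polymorphic (for the same
#' allele pair) in a comparison population as a function of its absolute
#' association effect size, with focal MAF and linked selection as
#' covariates to absorb ascertainment. Significance is a likelihood-ratio
#' chi-squared comparing models with and without the effect-size term.
#'
#' @param poly_flag logical/0-1 per site: polymorphic in the comparison
#'   population.
#' @param abs_beta absolute effect size per site.
#' @param lhm_maf focal MAF covariate.
#' @param linked_sel linked-selection covariate.
#' @return list: `or_per_unit` (odds ratio per unit `|beta|`), `ci` (95\%
#'   Wald), `lrt_chi2`, `df`, `p`, `separation` (TRUE if the response is
#'   degenerate or the fit separated; estimates are then NA).
#' @export
analysis_B_persistence_logit <- function(poly_flag, abs_beta, lhm_maf,
                                         linked_sel) {
  poly_flag <- as.integer(poly_flag)
  if (length(unique(poly_flag)) < 2L)
    return(list(or_per_unit = NA_real_, ci = c(NA_real_, NA_real_),
                lrt_chi2 = NA_real_, df = 1L, p = NA_real_,
                separation = TRUE))
  full <- stats::glm(poly_flag ~ abs_beta + lhm_maf + linked_sel,
                     family = stats::binomial())
  red <- stats::glm(poly_flag ~ lhm_maf + linked_sel,
                    family = stats::binomial())
  b <- stats::coef(full)["abs_beta"]
  se <- sqrt(diag(stats::vcov(full)))["abs_beta"]
  sep <- !full$converged || abs(b) > 20
  chi2 <- as.numeric(red$deviance - full$deviance)
  list(or_per_unit = if (sep) NA_real_ else unname(exp(b)),
       ci = if (sep) c(NA_real_, NA_real_) else
         unname(exp(b + c(-1.96, 1.96) * se)),
       lrt_chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
       separation = sep)
}

#' Binned Spearman correlation of comparison MAF and effect size
#'
#' Bins sites in two dimensions — residual focal MAF (`maf_bins`
#' quantiles) and absolute effect size (`beta_bins` quantiles) — draws one
#' site uniformly from each non-empty bin, and rank-correlates the drawn
#' sites' comparison-population MAF with their effect sizes. On a full
#' 20 x 100 grid, 2,000 sites are drawn.
#'
#' @param comp_maf comparison-population MAF per site.
#' @param abs_beta absolute effect size per site.
#' @param resid_lhm_maf residual (linked-selection-corrected) focal MAF.
#' @param maf_bins,beta_bins quantile-bin counts (defaults 20 and 100).
#' @param seed RNG seed for the within-bin draws.
#' @param empty_warn warn if more than this fraction of bins is empty
#'   (default 0.2).
#' @return list: `rho`, `p`, `n_drawn`, `n_bins_empty`.
#' @export
analysis_C_binned_spearman <- function(comp_maf, abs_beta, resid_lhm_maf,
                                       maf_bins = 20L, beta_bins = 100L,
                                       seed = 1L, empty_warn = 0.2) {
  qcut <- function(x, k) {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = k + 1L),
                                 na.rm = TRUE))
    cut(x, br, include.lowest = TRUE, labels = FALSE)
  }
  bm <- qcut(resid_lhm_maf, maf_bins)
  bb <- qcut(abs_beta, beta_bins)
  cell <- interaction(bm, bb, drop = FALSE)
  n_cells <- maf_bins * beta_bins
  idx_by_cell <- split(seq_along(comp_maf), cell)
  nonempty <- Filter(length, idx_by_cell)
  n_empty <- n_cells - length(nonempty)
  if (n_empty / n_cells > empty_warn)
    warning(sprintf("%d of %d MAF x effect-size bins are empty",
                    n_empty, n_cells))
  set.seed(seed)
  drawn <- vapply(nonempty, function(ii)
    ii[sample.int(length(ii), 1L)], integer(1))
  ct <- suppressWarnings(stats::cor.test(comp_maf[drawn], abs_beta[drawn],
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_drawn = length(drawn),
       n_bins_empty = n_empty)
}

#' Trans-specific polymorphism flags
#'
#' A site is trans-specific when (i) it is polymorphic in both the focal
#' panel and the comparison species, and (ii) the species' segregating
#' allele pair matches the focal pair (order-free). Anything else —
#' monomorphic in the species, or polymorphic for different variants — is
#' non-trans-specific.
#'
#' @param panel focal `genotype_panel`.
#' @param species a `comparison_panel` for the species.
#' @return logical per site.
#' @export
trans_specific_flags <- function(panel, species) {
  focal_poly <- panel_maf(panel) > 0
  sp_poly <- species$freq > 0 & species$freq < 1
  same_pair <- (species$sites$comp_ref == panel$sites$ref &
                  species$sites$comp_alt == panel$sites$alt) |
    (species$sites$comp_ref == panel$sites$alt &
       species$sites$comp_alt == panel$sites$ref)
  focal_poly & sp_poly & same_pair
}
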