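#' Per-call quality filter on depth and genotype quality
#'
#' Individual variant calls with depth below `min_depth` or genotype
#' quality below `min_gq` are set missing (strict `<`: a call with exactly
#' the threshold value is retained). Passing calls are unchanged.
#'
#' @param panel a `genotype_panel` with `dp` and `gq` matrices attached
#'   (e.g. from [read_panel_vcf()]).
#' @param min_depth,min_gq thresholds; defaults follow the standard funnel
#'   (DP < 10, GQ < 30 removed).
#' @return The panel with failing calls set to NA.
#' @export
filter_calls <- function(panel, min_depth = 10, min_gq = 30) {
  if (is.null(panel$dp)) stop("panel has no per-call DP field; cannot apply the depth filter")
  if (is.null(panel$gq)) stop("panel has no per-call GQ field; cannot apply the genotype-quality filter")
  fail <- (panel$dp < min_depth) | (panel$gq < min_gq)
  fail[is.na(fail)] <- TRUE
  panel$geno[fail] <- NA_integer_
  panel
}

#' Drop individuals with excessive missingness
#'
#' Individuals whose fraction of missing calls exceeds `max_missing`
#' (strict `>`; exactly 15\% missing is retained) are removed. Survivor
#' order is preserved.
#'
#' @param panel a `genotype_panel`.
#' @param max_missing maximum tolerated missing fraction (default 0.15).
#' @return Filtered panel; attribute `"removed"` lists dropped line ids.
#' @export
filter_individuals <- function(panel, max_missing = 0.15) {
  miss <- rowMeans(is.na(panel$geno))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all individuals exceed the missingness threshold")
  out <- new_genotype_panel(panel$lines[keep], panel$sites,
                            panel$geno[keep, , drop = FALSE])
  if (!is.null(panel$dp)) out$dp <- panel$dp[keep, , drop = FALSE]
  if (!is.null(panel$gq)) out$gq <- panel$gq[keep, , drop = FALSE]
  attr(out, "removed") <- panel$lines[!keep]
  out
}

#' Site-level filters: call rate, MAF and biallelic status
#'
#' Keeps sites with call rate `>= min_call_rate` across the retained
#' individuals, MAF strictly greater than `min_maf` (computed on called
#' alleles only; monomorphic sites fail), and — when alleles are checked —
#' a single REF/ALT pair. Returns the filtered panel together with a
#' `qc_report` recording the funnel.
#'
#' @param panel a `genotype_panel` (individual filter already applied:
#'   call rates refer to the retained individuals).
#' @param min_call_rate minimum per-site call rate (default 0.95).
#' @param min_maf sites with MAF \eqn{\le} this are removed (default 0.05,
#'   strict `>` retention).
#' @param biallelic_only drop sites whose ALT field contains a comma.
#' @return list with `panel` (filtered) and `report` (a `qc_report`).
#' @export
filter_sites <- function(panel, min_call_rate = 0.95, min_maf = 0.05,
                         biallelic_only = TRUE) {
  call_rate <- colMeans(!is.na(panel$geno))
  maf <- panel_maf(panel)
  multi <- grepl(",", panel$sites$alt, fixed = TRUE)
  fail_cr <- call_rate < min_call_rate
  fail_maf <- maf <= min_maf
  fail_bi <- biallelic_only & multi
  keep <- !(fail_cr | fail_maf | fail_bi)
  if (!any(keep)) stop("no sites survive the site filters")
  out <- subset_sites(panel, which(keep))
  report <- structure(list(
    input_sites = ncol(panel$geno),
    removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf & !fail_cr),
    removed_multiallelic = sum(fail_bi & !fail_cr & !fail_maf),
    final_sites = sum(keep),
    thresholds = list(min_call_rate = min_call_rate, min_maf = min_maf,
                      biallelic_only = biallelic_only)
  ), class = "qc_report")
  list(panel = out, report = report)
}

subset_sites <- function(panel, idx) {
  out <- new_genotype_panel(panel$lines, panel$sites[idx, , drop = FALSE],
                            panel$geno[, idx, drop = FALSE])
  rownames(out$sites) <- NULL
  if (!is.null(panel$dp)) out$dp <- panel$dp[, idx, drop = FALSE]
  if (!is.null(panel$gq)) out$gq <- panel$gq[, idx, drop = FALSE]
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Site QC funnel\n")
  cat(sprintf("  input sites:          %d\n", x$input_sites))
  cat(sprintf("  removed (call rate):  %d\n", x$removed_call_rate))
  cat(sprintf("  removed (MAF):        %d\n", x$removed_maf))
  cat(sprintf("  removed (multiallelic): %d\n", x$removed_multiallelic))
  cat(sprintf("  final sites:          %d\n", x$final_sites))
  invisible(x)
}

#' Greedy positional LD pruning
#'
#' Left-to-right scan within each arm: a site is kept unless it has
#' r-squared above `r2_max` with an already-kept site no more than
#' `window_bp` away (the later site of an offending pair is dropped).
#' After pruning, no retained pair within the window violates the
#' condition.
#'
#' @param panel a `genotype_panel` (MAF-filtered).
#' @param r2_max maximum tolerated pairwise r-squared (default 0.2).
#' @param window_bp pairing window in bp (default 10000).
#' @return integer vector of retained site indices (into `panel$sites`).
#' @export
ld_prune <- function(panel, r2_max = 0.2, window_bp = 10000) {
  keep <- logical(nrow(panel$sites))
  G <- impute_mean(panel$geno)
  for (arm in unique(panel$sites$arm)) {
    idx <- which(panel$sites$arm == arm)
    pos <- panel$sites$pos[idx]
    kept <- integer(0)
    for (k in seq_along(idx)) {
      near <- kept[pos[k] - pos[kept] <= window_bp]
      ok <- TRUE
      for (j in rev(near)) {
        if (stats::cor(G[, idx[k]], G[, idx[j]])^2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) { kept <- c(kept, k); keep[idx[k]] <- TRUE }
    }
  }
  which(keep)
}

# mean-impute missing genotypes per site (constant sites stay constant)
impute_mean <- function(G) {
  nas <- which(is.na(G))
  if (length(nas)) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    G[nas] <- mu[(nas - 1L) %/% nrow(G) + 1L]
  }
  G
}

#' Principal-component outlier screen against a reference panel
#'
#' Merges the focal and reference panels on the shared (LD-pruned) site
#' set, computes leading principal components of the centred genotype
#' matrix, and flags focal individuals whose score on any of the first
#' `n_pcs` axes exceeds `sd_threshold` focal-panel standard deviations —
#' a reproducible formalisation of the usual visual outlier call.
#'
#' @param panel focal `genotype_panel`.
#' @param reference_panel a second `genotype_panel` on the same sites
#'   (may be NULL to screen the focal panel alone).
#' @param n_pcs number of leading axes inspected (default 2).
#' @param sd_threshold outlier cut in focal-panel SD units (default 6).
#' @return list with `scores` (individuals x n_pcs, focal then reference),
#'   `outlier` (logical per focal individual), `focal` (row indicator).
#' @export
pca_outliers <- function(panel, reference_panel = NULL, n_pcs = 2,
                         sd_threshold = 6) {
  G <- impute_mean(panel$geno)
  focal <- rep(TRUE, nrow(G))
  if (!is.null(reference_panel)) {
    stopifnot(ncol(reference_panel$geno) == ncol(panel$geno))
    G <- rbind(G, impute_mean(reference_panel$geno))
    focal <- c(focal, rep(FALSE, nrow(reference_panel$geno)))
  }
  if (nrow(G) < n_pcs + 1L) stop("fewer individuals than n_pcs + 1")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(Gc, center = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  sds <- apply(scores[focal, , drop = FALSE], 2L, stats::sd)
  centres <- colMeans(scores[focal, , drop = FALSE])
  dev <- sweep(abs(sweep(scores[focal, , drop = FALSE], 2L, centres)), 2L, sds, "/")
  outlier <- apply(dev > sd_threshold, 1L, any)
  list(scores = scores, outlier = outlier, focal = focal)
}
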