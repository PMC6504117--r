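#' LD decay by pair class: candidate, control and mixed pairs
#'
#' For all same-arm site pairs within `max_dist` bp (self-pairs at d = 0
#' excluded), computes pairwise r-squared from the haplotype matrix and
#' classifies pairs as candidate/candidate, control/control or mixed.
#' r-squared is modelled as a declining exponential in distance,
#' \eqn{r^2(d) = a\,e^{-d/b} + c}, fitted by least squares over all pairs
#' with an analytically seeded start (a = first-bin mean minus last-bin
#' mean, c = last-bin mean, b = distance at half decay); residual
#' r-squared is then compared between classes with Wilcoxon rank-sum
#' tests. Elevated residual LD among candidate pairs in a distant
#' population is the signature of a selectively maintained haplotype.
#'
#' @param haplotypes 0/1 matrix (haplotypes x sites).
#' @param sites site table (`arm`, `pos`).
#' @param candidate logical per site.
#' @param max_dist maximum pair distance in bp (default 1000).
#' @param bin_bp distance-bin width for the binned means (default 25).
#' @param min_pairs classes with fewer pairs are flagged (default 10).
#' @return list: `pairs` (data.frame `dist`, `r2`, `class`, `resid`),
#'   `fit` (a, b, c), `binned` (per class x bin mean r2), `tests`
#'   (Wilcoxon p for cand vs control and cand vs mixed),
#'   `flagged_classes`.
#' @export
ld_class_comparison <- function(haplotypes, sites, candidate,
                                max_dist = 1000, bin_bp = 25,
                                min_pairs = 10L) {
  stopifnot(ncol(haplotypes) == nrow(sites))
  Hs <- scale(haplotypes)
  nh1 <- nrow(haplotypes) - 1L
  pair_list <- list()
  for (arm in unique(sites$arm)) {
    idx <- which(sites$arm == arm)
    pos <- sites$pos[idx]
    for (k in seq_along(idx)) {
      jj <- idx[pos > pos[k] & pos - pos[k] <= max_dist]
      if (!length(jj)) next
      sdk <- attr(Hs, "scaled:scale")[idx[k]]
      if (is.na(sdk) || sdk == 0) next
      r <- as.numeric(crossprod(Hs[, jj, drop = FALSE], Hs[, idx[k]])) / nh1
      r[!is.finite(r)] <- 0
      cl <- ifelse(candidate[idx[k]] & candidate[jj], "candidate",
                   ifelse(!candidate[idx[k]] & !candidate[jj], "control",
                          "mixed"))
      pair_list[[length(pair_list) + 1L]] <-
        data.frame(dist = sites$pos[jj] - pos[k], r2 = r^2, class = cl,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(pair_list)) stop("no site pairs within max_dist")
  pairs <- do.call(rbind, pair_list)

  bins <- pmin(floor(pairs$dist / bin_bp), floor(max_dist / bin_bp) - 1L)
  bin_mean <- tapply(pairs$r2, bins, mean)
  a0 <- max(bin_mean[1] - bin_mean[length(bin_mean)], 0.01)
  c0 <- max(bin_mean[length(bin_mean)], 1e-4)
  half <- which(bin_mean <= c0 + a0 / 2)
  b0 <- if (length(half)) max((as.numeric(names(half)[1]) + 0.5) * bin_bp, bin_bp)
        else max_dist / 2
  fit <- tryCatch(
    stats::nls(r2 ~ a * exp(-dist / b) + c, data = pairs,
               start = list(a = a0, b = b0, c = c0),
               control = stats::nls.control(maxiter = 200, tol = 1e-8,
                                            warnOnly = TRUE)),
    error = function(e)
      minpack.lm::nlsLM(r2 ~ a * exp(-dist / b) + c, data = pairs,
                        start = list(a = a0, b = b0, c = c0)))
  pairs$resid <- stats::resid(fit)

  cls <- c("candidate", "control", "mixed")
  counts <- table(factor(pairs$class, levels = cls))
  flagged <- cls[counts < min_pairs]
  wt <- function(c1, c2) {
    x <- pairs$resid[pairs$class == c1]
    y <- pairs$resid[pairs$class == c2]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    stats::wilcox.test(x, y)$p.value
  }
  binned <- tapply(pairs$r2, list(pairs$class, bins), mean)
  list(pairs = pairs, fit = stats::coef(fit), binned = binned,
       tests = list(candidate_vs_control = wt("candidate", "control"),
                    candidate_vs_mixed = wt("candidate", "mixed")),
       flagged_classes = flagged)
}
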