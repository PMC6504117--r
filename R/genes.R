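#' Build the gene-level analysis table
#'
#' A gene is antagonistic if at least one candidate SNP falls inside its
#' extended region (gene coordinates, 1-based inclusive, padded by
#' `flank_bp` on both sides). Gene-level covariates (sex-bias value and
#' significance class, tissue-specificity tau, PPI count) are joined from
#' the annotation set. Sex-limited genes — those in the most extreme
#' `trim` quantiles of the sex-bias distribution on either side — are
#' flagged so tau-based comparisons can exclude them.
#'
#' @param annotations an `annotation_set`.
#' @param sites site table of the analysed panel.
#' @param candidate logical per site.
#' @param flank_bp extension around gene coordinates (default 5000).
#' @param trim tail mass trimmed per side for the sex-limited flag
#'   (default 0.05).
#' @return data.frame: `gene`, `antagonistic`, `n_candidate_snps`,
#'   `log2_mf`, `sexbias_significant`, `tau`, `ppi`, `sex_limited`,
#'   `adult_expressed`.
#' @export
build_gene_table <- function(annotations, sites, candidate, flank_bp = 5000,
                             trim = 0.05) {
  genes <- annotations$genes
  ncand <- integer(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    hit <- sites$arm == genes$arm[gi] &
      sites$pos >= genes$start[gi] - flank_bp &
      sites$pos <= genes$end[gi] + flank_bp
    ncand[gi] <- sum(candidate & hit)
  }
  sb <- annotations$sexbias[match(genes$gene, annotations$sexbias$gene), ]
  qs <- stats::quantile(sb$log2_mf, c(trim, 1 - trim), na.rm = TRUE)
  taus <- apply(annotations$tissue_expr[genes$gene, , drop = FALSE], 1L, tau)
  data.frame(gene = genes$gene,
             antagonistic = ncand > 0L,
             n_candidate_snps = ncand,
             log2_mf = sb$log2_mf,
             sexbias_significant = sb$significant,
             tau = taus,
             ppi = as.integer(annotations$ppi[genes$gene]),
             sex_limited = sb$log2_mf < qs[1] | sb$log2_mf > qs[2],
             adult_expressed = rowSums(annotations$tissue_expr[genes$gene, ,
                                                               drop = FALSE] > 0) > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tissue-specificity index tau
#'
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (n - 1)} with
#' \eqn{\hat x_i = x_i / \max_i x_i}: 0 for uniform expression across
#' tissues, 1 for single-tissue expression. Invariant to positive
#' rescaling of the row.
#'
#' @param x non-negative expression values over >= 2 tissues.
#' @return tau in `[0, 1]`; NA (with a warning) for an all-zero row.
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least 2 tissues")
  if (any(x < 0)) stop("expression values must be non-negative")
  mx <- max(x)
  if (mx == 0) {
    warning("all-zero expression row: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Chi-squared test of sex-biased expression among antagonistic genes
#'
#' The expected count of significantly sex-biased antagonistic genes is
#' the background sex-biased fraction times the number of antagonistic
#' genes; a 1-df chi-squared compares observed and expected over the
#' two-cell (biased / unbiased) table. The deficit is
#' \eqn{100\,(E - O)/E} percent.
#'
#' @param gene_table from [build_gene_table()], or NULL when the counts
#'   are given directly.
#' @param observed,expected,n_antagonistic direct-count interface.
#' @return list: `observed`, `expected`, `chi2`, `p`, `deficit_pct`.
#' @export
sexbias_class_test <- function(gene_table = NULL, observed = NULL,
                               expected = NULL, n_antagonistic = NULL) {
  if (!is.null(gene_table)) {
    n_antagonistic <- sum(gene_table$antagonistic)
    observed <- sum(gene_table$antagonistic & gene_table$sexbias_significant)
    expected <- mean(gene_table$sexbias_significant) * n_antagonistic
  }
  stopifnot(!is.null(observed), !is.null(expected))
  deficit <- 100 * (expected - observed) / expected
  chi2 <- if (!is.null(n_antagonistic)) {
    e2 <- n_antagonistic - expected
    (observed - expected)^2 / expected +
      ((n_antagonistic - observed) - e2)^2 / e2
  } else NA_real_
  list(observed = observed, expected = expected, chi2 = chi2,
       p = if (is.na(chi2)) NA_real_ else
         stats::pchisq(chi2, 1, lower.tail = FALSE),
       deficit_pct = deficit)
}

#' Quantitative sex-bias analyses of antagonistic status
#'
#' Three views of how antagonism relates to the degree of expression sex
#' bias `|log2(M/F)|`: a Wilcoxon rank-sum comparison between antagonistic
#' and nonantagonistic genes; a binomial (logit) GLM likelihood-ratio test
#' of the quadratic term (does antagonism probability peak at zero bias?);
#' and a quartic-vs-quadratic LRT probing a twin-peaks shape.
#'
#' @param gene_table from [build_gene_table()].
#' @return list: `wilcox` (W, p), `quadratic` (chi2, df, p),
#'   `quartic` (chi2, df, p).
#' @export
sexbias_quantitative <- function(gene_table) {
  gt <- gene_table[!is.na(gene_table$log2_mf), ]
  x <- abs(gt$log2_mf)
  flag <- gt$antagonistic
  w <- stats::wilcox.test(x[flag], x[!flag])
  m1 <- stats::glm(flag ~ x, family = stats::binomial())
  m2 <- stats::glm(flag ~ x + I(x^2), family = stats::binomial())
  m4 <- stats::glm(flag ~ x + I(x^2) + I(x^3) + I(x^4),
                   family = stats::binomial())
  lrt <- function(small, big) {
    chi2 <- as.numeric(small$deviance - big$deviance)
    df <- small$df.residual - big$df.residual
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  list(wilcox = list(W = unname(w$statistic), p = w$p.value),
       quadratic = lrt(m1, m2), quartic = lrt(m2, m4))
}

#' Quasipoisson GLM of protein-protein interaction counts
#'
#' Log-link count regression of PPI degree on antagonistic status with a
#' free dispersion parameter; significance by dispersion-adjusted F-test.
#'
#' @param counts non-negative integer PPI counts per gene.
#' @param antagonistic logical per gene.
#' @return list: `coef` (log rate ratio), `F`, `p`, `dispersion`.
#' @export
ppi_glm <- function(counts, antagonistic) {
  if (stats::var(counts) == 0) stop("zero-variance PPI counts")
  fit <- stats::glm(counts ~ antagonistic, family = stats::quasipoisson())
  an <- stats::anova(fit, test = "F")
  list(coef = unname(stats::coef(fit)[2]),
       F = an$F[2], p = an$`Pr(>F)`[2],
       dispersion = summary(fit)$dispersion)
}

#' Chi-squared overlap test between two gene sets
#'
#' Expected overlap under independence is `|A| |B| / |background|`; the
#' test is the 2x2 chi-squared without continuity correction.
#'
#' @param n_a,n_b set sizes; `n_bg` background size; `overlap` observed.
#' @param overlap observed overlap count.
#' @return list: `observed`, `expected`, `chi2`, `p`.
#' @export
overlap_chisq <- function(n_a, n_b, n_bg, overlap) {
  expected <- n_a * n_b / n_bg
  tab <- matrix(c(overlap, n_a - overlap,
                  n_b - overlap, n_bg - n_a - n_b + overlap), 2L)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(observed = overlap, expected = expected,
       chi2 = unname(ct$statistic), p = ct$p.value)
}
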