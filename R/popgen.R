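#' Sliding-window diversity statistics
#'
#' For each window: the number of segregating sites S, nucleotide
#' diversity pi (mean pairwise differences, summed over window sites as
#' \eqn{\sum_j 2 c_{1j} c_{0j} / (n(n-1))} for allele counts \eqn{c}),
#' Watterson's estimator \eqn{\theta_W = S / a_1}, and Tajima's D
#' \deqn{D = (\pi - \theta_W) / \sqrt{e_1 S + e_2 S (S-1)}}
#' with the standard constants derived from the haplotype count n
#' (\eqn{a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2}). D is undefined (NA)
#' when S = 0; such windows are excluded from downstream regressions.
#'
#' @param haplotypes 0/1 matrix, haplotypes x sites (no missing calls).
#' @param sites site table (`arm`, `pos` 1-based) matching the columns.
#' @param window,step window geometry in bp (defaults 1000 / 500).
#' @return data.frame: `arm`, `start`, `end` (0-based half-open), `S`,
#'   `pi`, `theta_w`, `tajima_d`.
#' @export
window_diversity <- function(haplotypes, sites, window = 1000L, step = 500L) {
  n <- nrow(haplotypes)
  if (n < 4L) stop("need at least 4 haplotypes")
  cnt1 <- colSums(haplotypes)
  cnt0 <- n - cnt1
  seg <- cnt1 > 0L & cnt0 > 0L
  pi_site <- 2 * cnt1 * cnt0 / (n * (n - 1))
  k <- tajima_constants(n)

  wins <- tile_windows(sites, window, step)
  wins$S <- NA_integer_
  wins$pi <- NA_real_
  wins$theta_w <- NA_real_
  wins$tajima_d <- NA_real_
  for (i in seq_len(nrow(wins))) {
    idx <- sites_in_window(sites, wins$arm[i], wins$start[i], wins$end[i])
    S <- sum(seg[idx])
    wins$S[i] <- S
    wins$pi[i] <- sum(pi_site[idx])
    wins$theta_w[i] <- S / k$a1
    if (S > 0L) {
      v <- k$e1 * S + k$e2 * S * (S - 1)
      wins$tajima_d[i] <- (wins$pi[i] - wins$theta_w[i]) / sqrt(v)
    }
  }
  wins
}

# Tajima's D normalising constants for n haplotypes
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Gaussian GLM of residual Tajima's D on window class
#'
#' Residualises window D on linked selection, then regresses the
#' residuals on the antagonistic-window flag; a positive coefficient
#' means elevated regional polymorphism at antagonistic windows, as
#' balancing selection predicts.
#'
#' @param d Tajima's D per window (NA = undefined, dropped).
#' @param antagonistic logical per window.
#' @param linked_sel linked-selection value per window.
#' @return list: `coef` (antagonistic effect on residual D), `F`, `df`,
#'   `p`, `n_windows`.
#' @export
window_diversity_test <- function(d, antagonistic, linked_sel) {
  ok <- !is.na(d) & !is.na(linked_sel)
  if (length(unique(antagonistic[ok])) < 2L)
    stop("both window classes must be present")
  rd <- residualize(d[ok], linked_sel[ok])
  fit <- stats::lm(rd ~ antagonistic[ok])
  an <- stats::anova(fit)
  list(coef = unname(stats::coef(fit)[2]), F = an$`F value`[1],
       df = an$Df, p = an$`Pr(>F)`[1], n_windows = sum(ok))
}

#' Hudson's F_ST with sample-size correction
#'
#' Per-site numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#' p_2(1-p_2)/(n_2-1)} and denominator \eqn{p_1(1-p_2) + p_2(1-p_1)};
#' windows (or any grouping) aggregate as the ratio of summed numerators
#' to summed denominators ("ratio of averages"), which never exceeds the
#' largest per-site ratio.
#'
#' @param p1,p2 allele frequencies in the two populations.
#' @param n1,n2 sample sizes (haplotype counts).
#' @param group optional grouping (e.g. window id); NULL gives one global
#'   estimate.
#' @return If `group` is NULL, a single F_ST; otherwise a named vector
#'   per group (NA where the denominator is 0).
#' @export
hudson_fst <- function(p1, p2, n1, n2, group = NULL) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (is.null(group)) {
    if (sum(den, na.rm = TRUE) == 0) return(NA_real_)
    return(sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE))
  }
  ns <- tapply(num, group, sum, na.rm = TRUE)
  ds <- tapply(den, group, sum, na.rm = TRUE)
  out <- ns / ds
  out[ds == 0] <- NA_real_
  out
}

#' Window F_ST between two comparison panels, residualised and compared
#'
#' Computes Hudson window F_ST from two panels' per-site frequencies,
#' residualises on linked selection, and contrasts antagonistic vs
#' nonantagonistic windows with a Wilcoxon rank-sum test (F_ST is far
#' from normal, so a rank test is used rather than a Gaussian GLM).
#'
#' @param comp1,comp2 `comparison_panel` objects on the same sites.
#' @param sites site table.
#' @param antagonistic logical per window (from [window_set_test()]
#'   order).
#' @param linked_sel linked-selection value per window.
#' @param window,step window geometry.
#' @return list: `fst` (per window), `W`, `p`, `median_diff` (antagonistic
#'   minus nonantagonistic median residual F_ST).
#' @export
window_fst_test <- function(comp1, comp2, sites, antagonistic, linked_sel,
                            window = 1000L, step = 500L) {
  wins <- tile_windows(sites, window, step)
  stopifnot(nrow(wins) == length(antagonistic))
  n1 <- nrow(comp1$haplotypes)
  n2 <- nrow(comp2$haplotypes)
  fst <- rep(NA_real_, nrow(wins))
  for (i in seq_len(nrow(wins))) {
    idx <- sites_in_window(sites, wins$arm[i], wins$start[i], wins$end[i])
    if (!length(idx)) next
    fst[i] <- hudson_fst(comp1$freq[idx], comp2$freq[idx], n1, n2)
  }
  ok <- !is.na(fst) & !is.na(linked_sel)
  rf <- residualize(fst[ok], linked_sel[ok])
  fa <- antagonistic[ok]
  if (length(unique(fa)) < 2L) stop("both window classes must be present")
  w <- stats::wilcox.test(rf[fa], rf[!fa])
  list(fst = fst, W = unname(w$statistic), p = w$p.value,
       median_diff = stats::median(rf[fa]) - stats::median(rf[!fa]))
}
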