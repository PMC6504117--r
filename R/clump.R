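#' Greedy LD clumping of association results
#'
#' Repeatedly takes the most significant unclaimed SNP with
#' `p <= p_index_max` as an index SNP and claims every unclaimed SNP with
#' `p <= p_member_max` within `dist_bp` on the same arm whose r-squared
#' with the index exceeds `r2_min`. Returns cluster memberships and the
#' independent-cluster count.
#'
#' @param assoc per-SNP result data.frame with `p` (row order = panel site
#'   order).
#' @param panel the `genotype_panel` the results refer to.
#' @param p_index_max index-SNP significance threshold (default 0.00093,
#'   the least significant candidate in the reference analysis).
#' @param r2_min r-squared threshold for membership (default 0.4, strict
#'   `>`).
#' @param dist_bp distance threshold (default 10000).
#' @param p_member_max member threshold (defaults to `p_index_max`).
#' @return list: `cluster` (integer id per SNP, NA if unclaimed),
#'   `index` (site indices of index SNPs), `n_clusters`.
#' @export
clump <- function(assoc, panel, p_index_max = 0.00093, r2_min = 0.4,
                  dist_bp = 10000, p_member_max = p_index_max) {
  m <- nrow(assoc)
  stopifnot(m == nrow(panel$sites))
  G <- impute_mean(panel$geno)
  cluster <- rep(NA_integer_, m)
  claimed <- rep(FALSE, m)
  eligible_index <- !is.na(assoc$p) & assoc$p <= p_index_max
  eligible_member <- !is.na(assoc$p) & assoc$p <= p_member_max
  index <- integer(0)
  cid <- 0L
  repeat {
    open <- which(eligible_index & !claimed)
    if (!length(open)) break
    i <- open[which.min(assoc$p[open])]
    cid <- cid + 1L
    cluster[i] <- cid
    claimed[i] <- TRUE
    index <- c(index, i)
    near <- which(eligible_member & !claimed &
                    panel$sites$arm == panel$sites$arm[i] &
                    abs(panel$sites$pos - panel$sites$pos[i]) <= dist_bp)
    for (j in near) {
      if (stats::cor(G[, i], G[, j])^2 > r2_min) {
        cluster[j] <- cid
        claimed[j] <- TRUE
      }
    }
  }
  list(cluster = cluster, index = index, n_clusters = cid)
}

#' Permutation test of candidate-SNP clustering
#'
#' The statistic is the median distance between adjacent candidate SNPs on
#' the same chromosome arm. Candidate labels are permuted among all SNPs
#' of the stratum `n_perm` times; the p-value is the proportion of
#' permuted medians less than or equal to the observed one (small p =
#' candidates are more tightly clustered than random SNPs). Autosomes and
#' the X chromosome are analysed as separate strata to accommodate their
#' different SNP densities.
#'
#' @param sites site table (`arm`, `pos`).
#' @param candidate logical per site.
#' @param n_perm permutations (default 1000).
#' @param x_arm name of the X-chromosome arm (default "X").
#' @param seed RNG seed.
#' @return data.frame per stratum: `stratum`, `n_candidates`,
#'   `median_distance`, `p` (NA when a stratum has fewer than 2
#'   candidates).
#' @export
cluster_permutation_test <- function(sites, candidate, n_perm = 1000L,
                                     x_arm = "X", seed = 1L) {
  set.seed(seed)
  strata <- list(autosome = sites$arm != x_arm, X = sites$arm == x_arm)
  res <- lapply(names(strata), function(sn) {
    in_s <- strata[[sn]]
    if (!any(in_s)) return(NULL)
    cand <- candidate & in_s
    med_obs <- median_adjacent_distance(sites, cand)
    if (is.na(med_obs))
      return(data.frame(stratum = sn, n_candidates = sum(cand),
                        median_distance = NA_real_, p = NA_real_))
    k <- sum(cand)
    idx_s <- which(in_s)
    perm_med <- vapply(seq_len(n_perm), function(i) {
      lab <- logical(nrow(sites))
      lab[sample(idx_s, k)] <- TRUE
      median_adjacent_distance(sites, lab)
    }, numeric(1))
    data.frame(stratum = sn, n_candidates = k, median_distance = med_obs,
               p = mean(perm_med <= med_obs, na.rm = TRUE))
  })
  do.call(rbind, res)
}

# median distance between consecutive flagged sites within arms
median_adjacent_distance <- function(sites, flag) {
  d <- unlist(lapply(unique(sites$arm), function(arm) {
    p <- sort(sites$pos[flag & sites$arm == arm])
    if (length(p) >= 2L) diff(p) else numeric(0)
  }))
  if (!length(d)) return(NA_real_)
  stats::median(d)
}
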