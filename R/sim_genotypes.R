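#' Simulate a haploid genotype panel with block-wise linkage disequilibrium
#'
#' Generates `n_lines` haploid genomes over the configured chromosome arms
#' using a haplotype-copying scheme: each arm carries `n_founders` founder
#' haplotypes, and every line copies a founder left-to-right, switching to a
#' random founder between adjacent sites with probability
#' `1 - exp(-d / ld_block_bp)` for inter-site distance `d`. This produces
#' approximately exponential r-squared decay with scale `ld_block_bp`
#' (independent sites in the limit `ld_block_bp = 0`). Realised minor allele
#' frequencies are nudged back inside `target_maf_range` by flipping the
#' minimal number of random carriers, so downstream MAF filters see the
#' intended spectrum.
#'
#' @param config a [sim_config()] object.
#' @return A `genotype_panel`: list with `lines` (ids), `sites` (data.frame
#'   `arm`, `pos` (1-based bp), `ref`, `alt`), and `geno`, an
#'   `n_lines x n_sites` 0/1 integer matrix (NA = missing; none are missing
#'   at generation time).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_lines
  m_arm <- config$snps_per_arm
  bases <- c("A", "C", "G", "T")

  geno_list <- vector("list", length(config$arms))
  site_list <- vector("list", length(config$arms))
  for (ai in seq_along(config$arms)) {
    arm <- config$arms[ai]
    pos <- sort(sample.int(config$arm_length_bp, m_arm, replace = FALSE))
    d <- diff(pos)
    # founder haplotypes: a latent Gaussian AR(1) along the arm (scale
    # ld_block_bp) thresholded at per-site target frequencies, so nearby
    # sites are correlated across founders and LD decays with distance
    p_t <- stats::runif(m_arm, config$target_maf_range[1], config$target_maf_range[2])
    K <- config$n_founders
    z <- matrix(0, K, m_arm)
    z[, 1L] <- stats::rnorm(K)
    phi <- if (config$ld_block_bp > 0) exp(-d / config$ld_block_bp) else rep(0, m_arm - 1L)
    for (j in seq_len(m_arm - 1L))
      z[, j + 1L] <- phi[j] * z[, j] + sqrt(1 - phi[j]^2) * stats::rnorm(K)
    founders <- matrix(0L, K, m_arm)
    for (j in seq_len(m_arm))
      founders[z[, j] <= stats::qnorm(p_t[j]), j] <- 1L

    p_switch <- if (config$ld_block_bp > 0) 1 - exp(-d / config$ld_block_bp) else rep(1, m_arm - 1L)

    G <- matrix(0L, n, m_arm)
    cur <- sample.int(config$n_founders, n, replace = TRUE)
    G[, 1L] <- founders[cbind(cur, 1L)]
    for (j in seq_len(m_arm - 1L)) {
      sw <- stats::runif(n) < p_switch[j]
      if (any(sw)) cur[sw] <- sample.int(config$n_founders, sum(sw), replace = TRUE)
      G[, j + 1L] <- founders[cbind(cur, j + 1L)]
    }

    G <- repair_maf(G, config$target_maf_range)

    ref <- sample(bases, m_arm, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    site_list[[ai]] <- data.frame(arm = arm, pos = pos, ref = ref, alt = alt,
                                  stringsAsFactors = FALSE)
    geno_list[[ai]] <- G
  }

  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  geno <- do.call(cbind, geno_list)
  lines <- sprintf("line_%03d", seq_len(n))
  rownames(geno) <- lines
  colnames(geno) <- paste0(sites$arm, ":", sites$pos)
  new_genotype_panel(lines, sites, geno)
}

# flip the minimal number of random carriers/non-carriers so every site's
# MAF lands inside [lo, hi]; preserves LD structure except at repaired sites
repair_maf <- function(G, range) {
  n <- nrow(G)
  lo_cnt <- ceiling(range[1] * n)
  hi_cnt <- floor(range[2] * n)
  for (j in seq_len(ncol(G))) {
    cnt <- sum(G[, j])
    mac <- min(cnt, n - cnt)
    if (mac < lo_cnt) {
      need <- lo_cnt - mac
      from <- if (cnt <= n - cnt) which(G[, j] == 0L) else which(G[, j] == 1L)
      idx <- sample(from, need)
      G[idx, j] <- 1L - G[idx, j]
    } else if (mac > hi_cnt) {
      need <- mac - hi_cnt
      from <- if (cnt <= n - cnt) which(G[, j] == 1L) else which(G[, j] == 0L)
      idx <- sample(from, need)
      G[idx, j] <- 1L - G[idx, j]
    }
  }
  G
}

new_genotype_panel <- function(lines, sites, geno) {
  stopifnot(nrow(geno) == length(lines), ncol(geno) == nrow(sites))
  for (arm in unique(sites$arm)) {
    p <- sites$pos[sites$arm == arm]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within an arm")
  }
  structure(list(lines = lines, sites = sites, geno = geno),
            class = "genotype_panel")
}

#' Per-site minor allele frequency of a haploid panel
#'
#' Computed on called (non-missing) alleles only; monomorphic sites get 0.
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector in `[0, 0.5]`, one entry per site.
#' @export
panel_maf <- function(panel) {
  p <- colMeans(panel$geno, na.rm = TRUE)
  p[is.nan(p)] <- 0
  pmin(p, 1 - p)
}

#' Per-site alternate-allele frequency
#' @param panel a `genotype_panel`.
#' @return numeric vector in `[0, 1]`.
#' @export
panel_alt_freq <- function(panel) {
  p <- colMeans(panel$geno, na.rm = TRUE)
  p[is.nan(p)] <- 0
  p
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("Haploid genotype panel: %d lines x %d sites over arms %s\n",
              length(x$lines), nrow(x$sites),
              paste(unique(x$sites$arm), collapse = ",")))
  cat(sprintf("  missing calls: %.2f%%; median MAF %.3f\n",
              100 * miss, stats::median(panel_maf(x))))
  invisible(x)
}

#' Pairwise r-squared between two haploid genotype vectors
#'
#' Squared Pearson correlation on jointly called entries; 0 when either
#' vector is constant.
#' @param x,y 0/1 vectors (NA allowed).
#' @return scalar in `[0, 1]`.
#' @export
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}
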