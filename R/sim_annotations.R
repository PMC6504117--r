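#' Simulate functional annotations, gene metadata and a linked-selection track
#'
#' Stands in for the external annotation resources a real analysis would
#' consume: per-site functional consequence categories, a gene model (genes
#' tiled along each arm, sites assigned by position), gene-level sex-bias in
#' expression drawn from a two-component mixture (a narrow unbiased
#' component and a wide biased one, with a significance flag), a
#' genes-x-tissues expression matrix with variable tissue specificity,
#' protein-protein interaction counts, and a spatially autocorrelated
#' linked-selection value per 1,000-bp window (AR(1) along each arm). All
#' tables are synthetic and labelled as such.
#'
#' @param panel a `genotype_panel`.
#' @param config a [sim_config()].
#' @param category_probs named numeric vector of per-site category
#'   probabilities (must sum to 1).
#' @param n_tissues number of tissues in the expression matrix.
#' @param gene_length_bp,gene_gap_bp gene model geometry.
#' @param seed_offset decouples this generator's stream from the others.
#' @return An `annotation_set`: list with `site_category` (factor per site),
#'   `site_gene` (gene id or NA per site), `genes` (data.frame: `gene`,
#'   `arm`, `start`, `end` 1-based inclusive), `sexbias` (data.frame:
#'   `gene`, `log2_mf`, `significant`), `tissue_expr` (genes x tissues,
#'   non-negative), `ppi` (named integer per gene), `linked_sel`
#'   (data.frame: `arm`, `start`, `end` 0-based half-open 1,000-bp windows,
#'   `value`).
#' @export
simulate_annotations <- function(panel, config,
                                 category_probs = c(missense = 0.05,
                                                    synonymous = 0.10,
                                                    intron = 0.25,
                                                    `5'UTR` = 0.03,
                                                    `3'UTR` = 0.05,
                                                    upstream = 0.12,
                                                    downstream = 0.12,
                                                    intergenic = 0.26,
                                                    splice_region = 0.02),
                                 n_tissues = 10L,
                                 gene_length_bp = 3000L, gene_gap_bp = 2000L,
                                 seed_offset = 3L) {
  validate_sim_config(config)
  if (abs(sum(category_probs) - 1) > 1e-8)
    stop("category_probs must sum to 1")
  set.seed(config$seed + seed_offset)
  m <- nrow(panel$sites)

  site_category <- factor(
    sample(names(category_probs), m, replace = TRUE, prob = category_probs),
    levels = names(category_probs))

  # gene model: genes tiled with gaps along each arm
  genes <- do.call(rbind, lapply(unique(panel$sites$arm), function(arm) {
    starts <- seq(1L, config$arm_length_bp - gene_length_bp,
                  by = gene_length_bp + gene_gap_bp)
    data.frame(gene = sprintf("FBgn_%s_%03d", arm, seq_along(starts)),
               arm = arm, start = starts, end = starts + gene_length_bp - 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  site_gene <- rep(NA_character_, m)
  for (arm in unique(panel$sites$arm)) {
    si <- which(panel$sites$arm == arm)
    ga <- genes[genes$arm == arm, ]
    hit <- findInterval(panel$sites$pos[si], ga$start)
    ok <- hit >= 1L & panel$sites$pos[si] <= ga$end[pmax(hit, 1L)]
    site_gene[si[ok]] <- ga$gene[hit[ok]]
  }
  site_gene[site_category == "intergenic"] <- NA_character_

  ng <- nrow(genes)
  biased <- stats::runif(ng) < 0.3
  log2_mf <- ifelse(biased, stats::rnorm(ng, 0, 1.5), stats::rnorm(ng, 0, 0.15))
  sexbias <- data.frame(gene = genes$gene, log2_mf = log2_mf,
                        significant = biased & abs(log2_mf) > 0.5,
                        stringsAsFactors = FALSE)

  # tissue expression: gamma draws; a random subset of genes is
  # tissue-specific (expression concentrated in one tissue)
  expr <- matrix(stats::rgamma(ng * n_tissues, shape = 2, rate = 0.5),
                 ng, n_tissues,
                 dimnames = list(genes$gene, sprintf("tissue_%02d", seq_len(n_tissues))))
  spec <- stats::runif(ng) < 0.25
  for (i in which(spec)) {
    keep <- sample.int(n_tissues, 1L)
    expr[i, -keep] <- expr[i, -keep] * 0.02
  }

  ppi <- stats::rnbinom(ng, mu = 6, size = 1.2)
  names(ppi) <- genes$gene

  linked_sel <- do.call(rbind, lapply(unique(panel$sites$arm), function(arm) {
    starts <- seq(0L, config$arm_length_bp - 1000L, by = 1000L)
    v <- as.numeric(stats::arima.sim(list(ar = 0.9), length(starts))) * 0.1 + 0.8
    data.frame(arm = arm, start = starts, end = starts + 1000L, value = v,
               stringsAsFactors = FALSE)
  }))
  rownames(linked_sel) <- NULL

  structure(list(site_category = site_category, site_gene = site_gene,
                 genes = genes, sexbias = sexbias, tissue_expr = expr,
                 ppi = ppi, linked_sel = linked_sel),
            class = "annotation_set")
}

#' Per-site linked-selection value looked up from the window track
#'
#' @param sites site table (`arm`, `pos`, 1-based).
#' @param linked_sel window track (`arm`, `start`, `end` 0-based half-open,
#'   `value`).
#' @return numeric per site (NA where no window covers the site).
#' @export
site_linked_sel <- function(sites, linked_sel) {
  out <- rep(NA_real_, nrow(sites))
  for (arm in unique(sites$arm)) {
    si <- which(sites$arm == arm)
    tr <- linked_sel[linked_sel$arm == arm, ]
    tr <- tr[order(tr$start), ]
    idx <- findInterval(sites$pos[si] - 1L, tr$start)
    ok <- idx >= 1L & (sites$pos[si] - 1L) < tr$end[pmax(idx, 1L)]
    out[si[ok]] <- tr$value[idx[ok]]
  }
  out
}
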