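#' Write a haploid genotype panel to VCF v4.2
#'
#' Emits one sample column per line with a haploid `GT:DP:GQ` FORMAT.
#' Missing genotypes become `.`. Per-call depth and genotype quality can be
#' supplied as matrices (same shape as `panel$geno`) or as the attached
#' `panel$dp` / `panel$gq`; otherwise constant defaults are written.
#'
#' @param panel a `genotype_panel`.
#' @param path output file path (plain text).
#' @param dp,gq integer matrices (lines x sites) or single values.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, dp = NULL, gq = NULL) {
  n <- length(panel$lines); m <- nrow(panel$sites)
  if (is.null(dp)) dp <- if (!is.null(panel$dp)) panel$dp else 30L
  if (is.null(gq)) gq <- if (!is.null(panel$gq)) panel$gq else 99L
  if (length(dp) == 1L) dp <- matrix(dp, n, m)
  if (length(gq) == 1L) gq <- matrix(gq, n, m)
  stopifnot(all(dim(dp) == c(n, m)), all(dim(gq) == c(n, m)))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=antagwas",
    paste0("##contig=<ID=", unique(panel$sites$arm), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$lines), collapse = "\t")
  )

  gt <- ifelse(is.na(panel$geno), ".", as.character(panel$geno))
  calls <- matrix(paste(gt, dp, gq, sep = ":"), n, m)
  body <- vapply(seq_len(m), function(j) {
    paste(c(panel$sites$arm[j], panel$sites$pos[j], ".",
            panel$sites$ref[j], panel$sites$alt[j], ".", "PASS", ".",
            "GT:DP:GQ", calls[, j]), collapse = "\t")
  }, character(1))

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a haploid VCF into a genotype panel
#'
#' Parses a VCF v4.2 with haploid `GT` calls via \pkg{vcfR} and attaches
#' per-call `DP` and `GQ` matrices when present, so [filter_calls()] can be
#' applied. Genotypes other than 0/1/'.' raise an error (the pipeline is
#' strictly biallelic haploid).
#'
#' @param path VCF file path.
#' @return A `genotype_panel` with `dp` and `gq` matrices attached (NULL if
#'   the FORMAT lacks them).
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(arm = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")           # sites x samples
  geno <- t(gt)
  bad <- !(geno %in% c("0", "1", ".", NA))
  if (any(bad)) stop("non-haploid or multiallelic genotype encountered: ",
                     paste(unique(geno[bad])[1:3], collapse = ","))
  mode(geno) <- "character"
  g <- matrix(NA_integer_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  g[geno == "0"] <- 0L
  g[geno == "1"] <- 1L
  lines <- rownames(g)
  colnames(g) <- paste0(sites$arm, ":", sites$pos)
  panel <- new_genotype_panel(lines, sites, g)

  fmt <- unique(v@gt[, "FORMAT"])
  panel$dp <- if (any(grepl("DP", fmt))) {
    dpm <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dimnames(dpm) <- dimnames(g); dpm
  }
  panel$gq <- if (any(grepl("GQ", fmt))) {
    gqm <- t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    dimnames(gqm) <- dimnames(g); gqm
  }
  panel
}

#' Write the standard pipeline TSV tables
#'
#' Plain tab-separated writers for the assay table, line-fitness table,
#' per-SNP association results, window results and linked-selection track.
#' One function per table would be ceremony; this dispatches on a `what`
#' tag and always writes `NA` as `NA`, no quotes, no row names.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
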