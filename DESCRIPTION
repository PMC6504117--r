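Package: antagwas
Title: Sexually Antagonistic Variant Detection and Balancing-Selection Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for mapping sexually antagonistic genetic variation from
    hemiclonal sex-specific fitness assays. Covers genotype and assay quality
    control, Box-Cox normalisation and antagonism/concordant fitness indices,
    Bayesian estimation of the cross-sex genetic (co)variance matrix, LD- and
    MAF-weighted kinship construction, REML SNP-heritability and mixed-model
    association with whitening-permutation empirical p-values, FDR candidate
    calling, window set-tests, LD clumping and clustering tests, heritability
    partitioning with circular-permutation nulls, gene-level enrichment and
    sex-bias analyses, and SNP-, window- and linkage-based tests of balancing
    selection against comparison populations (matched Monte-Carlo nulls,
    Tajima's D, Hudson's F_ST, LD decay, trans-specific polymorphism). A
    synthetic-data generator emulates hemiclonal genotype panels, vial-level
    fitness assays, comparison panels and functional annotations so the whole
    chain runs and is validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    MASS,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
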