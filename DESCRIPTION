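Package: twinqtl
Title: Discovery and Fine-Mapping of a Maternal Multiple-Birth QTL from
    Pedigree, Phenotype and Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for the genetic analysis of a rare binary
    calving trait (multiple birth) in dairy cattle. Implements the
    direct-maternal animal model with correlated calf and dam genetic effects
    (AI-REML variance components, BLUP breeding values, exact prediction-error
    variances and reliabilities, base-group standardization, genetic trend),
    Garrick-style de-regression of breeding values, a mixed-model single-SNP
    genome scan on de-regressed proofs with a VanRaden genomic relationship
    matrix, a BayesB Markov chain sampler with per-window genetic-variance
    partitioning, an exhaustive odd-length sliding-haplotype association scan,
    and LD-based prioritization of sequence variants against a top haplotype,
    including Mendelian-error quality control of a sequence panel. A
    self-contained herd simulator (multi-generation pedigree, phased
    block-LD genotypes, planted maternal QTL haplotype, dense sequence panel
    with graded LD) provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
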