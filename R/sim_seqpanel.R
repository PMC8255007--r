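#' Simulate a dense sequence-variant panel around the planted QTL
#'
#' Emits a whole-genome-sequence-like variant panel inside a window of the
#' QTL chromosome. Linked variants are built by copying each gamete's
#' planted-haplotype carrier indicator and flipping it with a per-variant
#' flip rate, which yields a controllable, graded LD (r-squared) ladder with
#' the haplotype; the variant with the smallest flip rate is the designated
#' causal proxy. Independent variants are drawn from per-variant allele
#' frequencies, unlinked to the haplotype. Missing genotypes, breed labels
#' and parent-offspring links for Mendelian checks are injected per
#' configuration.
#'
#' @param genotypes [simulate_genotypes()] output carrying a planted QTL.
#' @param config the [sim_config()]; its `seq_panel` element must be set.
#' @return An object of class `seq_panel`: list with `variants` (columns
#'   `chrom`, `pos`, `ref`, `alt`, `flip_rate`, `linked`), `geno` (samples x
#'   variants dosage matrix with `NA` for missing), `samples` (columns `id`,
#'   `breed`), and `families` (columns `child`, `sire`, `dam`; `NA` for an
#'   absent parent). The causal-proxy column index is in
#'   `attr(, "causal_proxy")`.
#' @export
simulate_seq_panel <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "phased_genotypes"), inherits(config, "sim_config"))
  sp <- config$seq_panel
  if (is.null(sp)) stop_twinqtl("config$seq_panel is not set")
  q <- attr(genotypes, "qtl")
  if (is.null(q)) stop_twinqtl("genotypes carry no planted QTL")
  map <- genotypes$map
  chrom_len <- config$chromosome_length
  if (sp$window[1] < 1 || sp$window[2] > chrom_len || sp$window[1] >= sp$window[2]) {
    stop_twinqtl("sequence-panel window lies outside the simulated map")
  }
  with_seed(child_seed(config$seed, 4), {
    idx <- q$marker_idx
    foc <- matrix(q$focal, nrow(genotypes$H1), length(idx), byrow = TRUE)
    c1 <- as.integer(rowSums(genotypes$H1[, idx, drop = FALSE] == foc) == length(idx))
    c2 <- as.integer(rowSums(genotypes$H2[, idx, drop = FALSE] == foc) == length(idx))

    n_all <- length(genotypes$ids)
    n_samp <- min(sp$n_samples %||% n_all, n_all)
    samp_rows <- sort(sample.int(n_all, n_samp))
    ids <- genotypes$ids[samp_rows]

    n_linked <- sp$n_linked
    flips <- rep(sp$flip_rates, length.out = n_linked)
    n_indep <- sp$n_independent
    n_var <- n_linked + n_indep
    pos <- sort(sample(seq(sp$window[1], sp$window[2]), n_var))
    linked_cols <- sort(sample.int(n_var, n_linked))

    geno <- matrix(NA_integer_, n_samp, n_var)
    flip_rate <- rep(NA_real_, n_var)
    k <- 0
    for (j in seq_len(n_var)) {
      if (j %in% linked_cols) {
        k <- k + 1
        f <- flips[k]
        flip_rate[j] <- f
        g1 <- abs(c1[samp_rows] - rbinom(n_samp, 1, f))
        g2 <- abs(c2[samp_rows] - rbinom(n_samp, 1, f))
        geno[, j] <- g1 + g2
      } else {
        p <- runif(1, 0.1, 0.5)
        geno[, j] <- rbinom(n_samp, 2, p)
      }
    }
    if (sp$missing_rate > 0) {
      miss <- runif(length(geno)) < sp$missing_rate
      geno[miss] <- NA_integer_
    }

    acgt <- c("A", "C", "G", "T")
    ref <- sample(acgt, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(acgt, r), 1), "")
    variants <- data.frame(
      chrom = q$chrom, pos = pos, ref = ref, alt = unname(alt),
      flip_rate = flip_rate, linked = seq_len(n_var) %in% linked_cols
    )
    rownames(geno) <- ids
    colnames(geno) <- sprintf("var_%d_%d", q$chrom, pos)

    samples <- data.frame(
      id = ids,
      breed = sample(sp$breeds, n_samp, replace = TRUE)
    )

    # family links are attached afterwards via panel_families()
    fam <- data.frame(child = integer(0), sire = integer(0), dam = integer(0))

    out <- structure(
      list(variants = variants, geno = geno, samples = samples, families = fam),
      class = "seq_panel"
    )
    lc <- which(variants$linked)
    attr(out, "causal_proxy") <- lc[which.min(variants$flip_rate[lc])]
    attr(out, "seed") <- config$seed
    out
  })
}

#' Attach pedigree-based family links to a sequence panel
#'
#' Fills the panel's `families` table with the sire/dam of every sampled
#' animal that is itself in the panel, yielding the duos and trios used by
#' [mendelian_error_rate()].
#'
#' @param panel a `seq_panel`.
#' @param pedigree the pedigree the panel animals came from.
#' @return The panel with an updated `families` element.
#' @export
panel_families <- function(panel, pedigree) {
  ids <- panel$samples$id
  row <- match(ids, pedigree$id)
  sire <- pedigree$sire[row]
  dam <- pedigree$dam[row]
  sire[!sire %in% ids] <- NA
  dam[!dam %in% ids] <- NA
  keep <- !is.na(sire) | !is.na(dam)
  panel$families <- data.frame(
    child = ids[keep], sire = sire[keep], dam = dam[keep]
  )
  panel
}
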