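#' Simulate phased genotypes down a pedigree
#'
#' Founder haplotypes are drawn from a finite pool with block-LD structure:
#' each chromosome is cut into blocks of `block_span` bp, each block carries
#' a small number of distinct allele patterns, and each pool haplotype picks
#' one pattern per block. Descendant haplotypes are produced by gene
#' dropping: each gamete is a recombined copy of the parent's two haplotypes
#' with crossovers placed as a Poisson process at `recomb_rate` per bp. When
#' a QTL is configured, a fixed number of pool haplotypes (matching the
#' target frequency) carry the focal allele pattern across the QTL window,
#' so the planted haplotype segregates at approximately its target frequency.
#'
#' @param pedigree a parents-first pedigree from [simulate_pedigree()].
#' @param config the [sim_config()] used to build the pedigree.
#' @return An object of class `phased_genotypes`: a list with `map` (columns
#'   `chrom`, `pos`, `id`, `ref`, `alt`; positions strictly increasing within
#'   a chromosome), integer matrices `H1` and `H2` (animals x markers, one
#'   row per pedigree animal, phased maternal/paternal haplotype alleles
#'   coded 0/1), and `ids`. The planted haplotype description is stored in
#'   `attr(, "qtl")`.
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(pedigree)
  if (config$n_chromosomes < 1 || config$snps_per_chromosome < 1) {
    stop_twinqtl("marker map is empty")
  }
  with_seed(child_seed(config$seed, 2), {
    map_list <- lapply(seq_len(config$n_chromosomes), function(chr) {
      pos <- sort(sample.int(config$chromosome_length,
        config$snps_per_chromosome,
        replace = FALSE
      ))
      acgt <- c("A", "C", "G", "T")
      ref <- sample(acgt, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(acgt, r), 1), "")
      data.frame(
        chrom = chr, pos = pos,
        id = sprintf("snp%d_%06d", chr, seq_along(pos)),
        ref = ref, alt = unname(alt)
      )
    })
    map <- do.call(rbind, map_list)
    m_total <- nrow(map)
    n <- nrow(pedigree)
    K <- config$founder_pool_size

    # founder haplotype pool with block structure
    pool <- matrix(0L, K, m_total)
    for (chr in seq_len(config$n_chromosomes)) {
      idx <- which(map$chrom == chr)
      block <- (map$pos[idx] - 1) %/% config$block_span
      for (b in unique(block)) {
        bidx <- idx[block == b]
        p <- runif(length(bidx), 0.1, 0.9)
        pats <- matrix(
          rbinom(config$variants_per_block * length(bidx), 1, rep(p, each = config$variants_per_block)),
          nrow = config$variants_per_block
        )
        pick <- sample.int(config$variants_per_block, K, replace = TRUE)
        pool[, bidx] <- pats[pick, , drop = FALSE]
      }
    }

    qtl_info <- NULL
    if (!is.null(config$qtl)) {
      q <- config$qtl
      widx <- which(map$chrom == q$chrom & map$pos >= q$start & map$pos <= q$end)
      if (length(widx) == 0) {
        stop_twinqtl("QTL window contains no markers")
      }
      focal <- pool[1, widx]
      n_carrier <- max(1L, round(K * q$target_freq))
      carriers <- sample.int(K, n_carrier)
      pool[carriers, widx] <- rep(focal, each = n_carrier)
      # make sure non-carrier pool haplotypes do not match the focal string
      non <- setdiff(seq_len(K), carriers)
      for (k in non) {
        if (all(pool[k, widx] == focal)) {
          flip <- sample(widx, 1)
          pool[k, flip] <- 1L - pool[k, flip]
        }
      }
      qtl_info <- list(
        marker_idx = widx, focal = focal, chrom = q$chrom,
        start = q$start, end = q$end, effect = q$effect,
        target_freq = q$target_freq
      )
    }

    H1 <- matrix(0L, n, m_total)
    H2 <- matrix(0L, n, m_total)
    rownames(H1) <- rownames(H2) <- pedigree$id
    founder_rows <- which(is.na(pedigree$sire) & is.na(pedigree$dam))
    H1[founder_rows, ] <- pool[sample.int(K, length(founder_rows), replace = TRUE), , drop = FALSE]
    H2[founder_rows, ] <- pool[sample.int(K, length(founder_rows), replace = TRUE), , drop = FALSE]

    pos_of <- map$pos
    idx_by_chrom <- split(seq_len(m_total), map$chrom)
    for (i in seq_len(n)) {
      si <- pedigree$sire[i]
      if (is.na(si)) next
      sr <- match(si, pedigree$id)
      dr <- match(pedigree$dam[i], pedigree$id)
      H1[i, ] <- recombine_gamete(
        H1[dr, ], H2[dr, ], idx_by_chrom, pos_of,
        config$recomb_rate, config$chromosome_length
      )
      H2[i, ] <- recombine_gamete(
        H1[sr, ], H2[sr, ], idx_by_chrom, pos_of,
        config$recomb_rate, config$chromosome_length
      )
    }

    out <- structure(
      list(map = map, H1 = H1, H2 = H2, ids = pedigree$id),
      class = "phased_genotypes"
    )
    attr(out, "qtl") <- qtl_info
    attr(out, "seed") <- config$seed
    out
  })
}

# One meiosis: recombined copy of the parent's two haplotypes.
recombine_gamete <- function(h1, h2, idx_by_chrom, pos, rate, chrom_len) {
  g <- integer(length(h1))
  for (idx in idx_by_chrom) {
    n_cross <- if (rate > 0) rpois(1, rate * chrom_len) else 0L
    start <- sample.int(2, 1)
    if (n_cross == 0) {
      g[idx] <- if (start == 1) h1[idx] else h2[idx]
    } else {
      cp <- sort(runif(n_cross, 1, chrom_len))
      seg <- findInterval(pos[idx], cp)
      use1 <- (seg + start) %% 2 == 1
      g[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  g
}

#' Allele dosages from phased genotypes
#'
#' @param genotypes a `phased_genotypes` object.
#' @return Integer matrix of alt-allele counts (0/1/2), animals x markers,
#'   with marker ids as column names.
#' @export
dosages <- function(genotypes) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  d <- genotypes$H1 + genotypes$H2
  colnames(d) <- genotypes$map$id
  d
}

#' Diplotype of the planted QTL haplotype
#'
#' Counts, for every animal, how many of its two phased haplotypes match the
#' planted focal allele string across the QTL window.
#'
#' @param genotypes a `phased_genotypes` object carrying a planted QTL.
#' @return Integer vector (0/1/2) named by animal id.
#' @export
qtl_diplotype <- function(genotypes) {
  q <- attr(genotypes, "qtl")
  if (is.null(q)) stop_twinqtl("genotypes carry no planted QTL")
  idx <- q$marker_idx
  c1 <- rowSums(genotypes$H1[, idx, drop = FALSE] ==
    matrix(q$focal, nrow(genotypes$H1), length(idx), byrow = TRUE)) == length(idx)
  c2 <- rowSums(genotypes$H2[, idx, drop = FALSE] ==
    matrix(q$focal, nrow(genotypes$H2), length(idx), byrow = TRUE)) == length(idx)
  setNames(as.integer(c1) + as.integer(c2), genotypes$ids)
}
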