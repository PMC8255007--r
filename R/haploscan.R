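#' Enumerate sliding haplotype windows
#'
#' For every odd haplotype length in `lengths` and every start marker such
#' that the window fits inside the segment, one window skeleton is
#' produced (start shifted SNP-wise). The total count is
#' `sum over L of max(0, m - L + 1)` for `m` markers in the segment.
#'
#' @param map marker map (`chrom`, `pos`, `id`).
#' @param segment `"chr:start-end"` string or list with `chrom`, `start`,
#'   `end` (bp, 1-based inclusive).
#' @param lengths odd window lengths in SNPs (default all odd 9..301).
#' @return `data.frame` with `chrom`, `first` and `last` (marker indices
#'   into `map`), `start`, `end` (bp of the flanking markers), `n_snps`.
#'   Empty (with a warning) if the segment holds fewer than `min(lengths)`
#'   markers.
#' @export
enumerate_windows <- function(map, segment, lengths = seq(9, 301, by = 2)) {
  if (any(lengths %% 2 == 0)) {
    stop_twinqtl("haplotype lengths must all be odd")
  }
  seg <- parse_segment(segment)
  idx <- which(map$chrom == seg$chrom & map$pos >= seg$start & map$pos <= seg$end)
  m <- length(idx)
  if (m < min(lengths)) {
    warning("segment holds ", m, " markers, fewer than the shortest window")
    return(data.frame(
      chrom = character(0), first = integer(0), last = integer(0),
      start = numeric(0), end = numeric(0), n_snps = integer(0)
    ))
  }
  out <- do.call(rbind, lapply(lengths[lengths <= m], function(L) {
    starts <- seq_len(m - L + 1)
    data.frame(
      chrom = seg$chrom, first = idx[starts], last = idx[starts + L - 1],
      start = map$pos[idx[starts]], end = map$pos[idx[starts + L - 1]],
      n_snps = L
    )
  }))
  rownames(out) <- NULL
  out
}

#' Haplotype alleles and dosages within a window
#'
#' Tallies the distinct haplotype allele strings across all `2n` phased
#' chromosomes in a window and counts, per animal, how many of its two
#' haplotypes match each string.
#'
#' @param phased a `phased_genotypes` object.
#' @param window one row of [enumerate_windows()] (or a list with `first`,
#'   `last` marker indices).
#' @return A list with `haplotypes` (`data.frame`: `allele_string`, `freq`,
#'   frequencies summing to 1) and `dosage` (animals x haplotypes integer
#'   matrix).
#' @export
haplotype_dosages <- function(phased, window) {
  if (!inherits(phased, "phased_genotypes")) {
    stop_twinqtl("phased genotypes required; run phasing first")
  }
  idx <- seq(window$first, window$last)
  k1 <- do.call(paste0, as.data.frame(phased$H1[, idx, drop = FALSE]))
  k2 <- do.call(paste0, as.data.frame(phased$H2[, idx, drop = FALSE]))
  tab <- table(c(k1, k2))
  strings <- names(tab)
  freq <- as.numeric(tab) / sum(tab)
  dos <- outer(k1, strings, "==") + outer(k2, strings, "==")
  colnames(dos) <- strings
  rownames(dos) <- phased$ids
  list(
    haplotypes = data.frame(allele_string = strings, freq = freq),
    dosage = dos
  )
}

#' Exhaustive sliding-haplotype association scan
#'
#' Tests every haplotype with frequency at least `min_freq` in every
#' enumerated window against the de-regressed response, using the same
#' eigen-rotated GLS core as [single_snp_scan()] with variance components
#' fixed at the null fit. Results are ranked by p-value (ties broken by
#' longer window first, then genomic start position).
#'
#' @param y de-regressed response (one value per animal in `phased`).
#' @param phased `phased_genotypes` for the same animals.
#' @param segment segment string or list (see [enumerate_windows()]).
#' @param null a [fit_null_model()] object on the same animals.
#' @param min_freq minimum focal-haplotype frequency (default 0.05).
#' @param lengths odd window lengths (default 9..301).
#' @param top_k keep the best `top_k` rows (default `Inf`, all).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`,
#'   `allele_string`, `freq`, `effect`, `se`, `p`, ranked as above. Empty
#'   with a warning if no haplotype passes the frequency floor.
#' @export
haplotype_scan <- function(y, phased, segment, null, min_freq = 0.05,
                           lengths = seq(9, 301, by = 2), top_k = Inf) {
  stopifnot(inherits(null, "null_model"))
  wins <- enumerate_windows(phased$map, segment, lengths)
  if (nrow(wins) == 0) {
    return(empty_hap_result())
  }
  n_anim <- length(phased$ids)
  win_id <- integer(0)
  strings <- character(0)
  freqs <- numeric(0)
  dos_cols <- list()
  for (w in seq_len(nrow(wins))) {
    hd <- haplotype_dosages(phased, wins[w, ])
    keep <- which(hd$haplotypes$freq >= min_freq & hd$haplotypes$freq < 1)
    if (length(keep) == 0) next
    win_id <- c(win_id, rep(w, length(keep)))
    strings <- c(strings, hd$haplotypes$allele_string[keep])
    freqs <- c(freqs, hd$haplotypes$freq[keep])
    dos_cols[[length(dos_cols) + 1]] <- hd$dosage[, keep, drop = FALSE]
  }
  if (length(win_id) == 0) {
    warning("no haplotype reaches the frequency floor ", min_freq)
    return(empty_hap_result())
  }
  out <- data.frame(
    chrom = wins$chrom[win_id], start = wins$start[win_id],
    end = wins$end[win_id], n_snps = wins$n_snps[win_id],
    allele_string = strings, freq = freqs
  )
  D <- do.call(cbind, dos_cols)
  core <- gls_scan_core(D, null)
  out$effect <- core$beta
  out$se <- core$se
  out$p <- core$p
  ord <- order(out$p, -out$n_snps, out$start)
  out <- out[ord, , drop = FALSE]
  if (is.finite(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

empty_hap_result <- function() {
  data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    n_snps = integer(0), allele_string = character(0), freq = numeric(0),
    effect = numeric(0), se = numeric(0), p = numeric(0)
  )
}

#' Effect of a diplotype on an auxiliary trait
#'
#' Fits the focal haplotype's diplotype dosage (0/1/2 copies) as a single
#' regressor on another trait's de-regressed response, with a polygenic
#' effect on the genomic relationship matrix to correct for stratification
#' (the same mixed-model GLS machinery as the scans).
#'
#' @param diplotype named dosage vector (0/1/2 copies of the focal
#'   haplotype).
#' @param trait_y named de-regressed response of the auxiliary trait.
#' @param grm genomic relationship matrix whose dimnames cover both vectors
#'   (or an unnamed matrix matching `trait_y`).
#' @return One-row `data.frame` with `effect`, `se`, `p`, `n`.
#' @export
diplotype_effect_on_trait <- function(diplotype, trait_y, grm) {
  ids <- intersect(names(diplotype), names(trait_y))
  if (length(ids) == 0 && length(diplotype) == length(trait_y)) {
    ids <- seq_along(trait_y)
    names(diplotype) <- names(trait_y) <- ids
    if (!is.null(dimnames(grm))) dimnames(grm) <- list(ids, ids)
  }
  if (length(ids) < 30) {
    stop_twinqtl(
      "only ", length(ids), " overlapping animals; at least 30 required"
    )
  }
  d <- diplotype[as.character(ids)]
  yv <- trait_y[as.character(ids)]
  G <- if (!is.null(dimnames(grm))) {
    grm[as.character(ids), as.character(ids)]
  } else {
    grm
  }
  null <- fit_null_model(as.numeric(yv), G)
  core <- gls_scan_core(matrix(as.numeric(d)), null)
  data.frame(effect = core$beta, se = core$se, p = core$p, n = length(ids))
}
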