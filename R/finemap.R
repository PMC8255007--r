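#' Mendelian error rates in a sequence panel
#'
#' Duo errors are opposing homozygotes between one genotyped parent and the
#' child; trio errors are child genotypes impossible given both parents
#' (each parent transmits one of its alleles). Rates are errors divided by
#' the non-missing tested transmissions, per variant and per sample (a
#' sample's tests are all family-variant combinations in which it takes
#' part). Families whose members are missing from the panel are skipped
#' with a warning.
#'
#' @param panel a `seq_panel` (see [simulate_seq_panel()]).
#' @param families `data.frame` with `child`, `sire`, `dam` (`NA` for an
#'   absent parent); defaults to `panel$families`.
#' @return List with `per_variant` and `per_sample` `data.frame`s (`errors`,
#'   `tested`, `rate`), and counts `n_duos`, `n_trios`.
#' @export
mendelian_error_rate <- function(panel, families = NULL) {
  fam <- families %||% panel$families
  geno <- panel$geno
  ids <- rownames(geno)
  n_var <- ncol(geno)
  var_err <- var_tst <- numeric(n_var)
  samp_err <- samp_tst <- setNames(numeric(length(ids)), ids)
  n_duos <- n_trios <- 0L

  if (!is.null(fam) && nrow(fam) > 0) {
    for (k in seq_len(nrow(fam))) {
      ch <- as.character(fam$child[k])
      pa <- as.character(fam$sire[k])
      ma <- as.character(fam$dam[k])
      pa <- if (!is.na(fam$sire[k]) && pa %in% ids) pa else NA
      ma <- if (!is.na(fam$dam[k]) && ma %in% ids) ma else NA
      if (!ch %in% ids || (is.na(pa) && is.na(ma))) {
        warning("family with child ", ch, " skipped: members not in panel")
        next
      }
      gc <- geno[ch, ]
      if (!is.na(pa) && !is.na(ma)) {
        n_trios <- n_trios + 1L
        gp <- geno[pa, ]
        gm <- geno[ma, ]
        ok <- !is.na(gc) & !is.na(gp) & !is.na(gm)
        err <- ok & !trio_consistent(gc, gp, gm)
        members <- c(ch, pa, ma)
      } else {
        n_duos <- n_duos + 1L
        gp <- geno[if (is.na(pa)) ma else pa, ]
        ok <- !is.na(gc) & !is.na(gp)
        err <- ok & abs(gc - gp) == 2
        members <- c(ch, if (is.na(pa)) ma else pa)
      }
      var_err <- var_err + err
      var_tst <- var_tst + ok
      for (mm in members) {
        samp_err[mm] <- samp_err[mm] + sum(err)
        samp_tst[mm] <- samp_tst[mm] + sum(ok)
      }
    }
  }
  list(
    per_variant = data.frame(
      variant = colnames(geno), errors = var_err, tested = var_tst,
      rate = ifelse(var_tst > 0, var_err / var_tst, 0)
    ),
    per_sample = data.frame(
      sample = ids, errors = unname(samp_err), tested = unname(samp_tst),
      rate = ifelse(samp_tst > 0, samp_err / samp_tst, 0)
    ),
    n_duos = n_duos, n_trios = n_trios
  )
}

# Child dosage possible given two parent dosages (one allele from each).
trio_consistent <- function(gc, gp, gm) {
  pa <- ifelse(gp == 1, NA, gp / 2) # transmitted allele, NA = either
  ma <- ifelse(gm == 1, NA, gm / 2)
  lo <- ifelse(is.na(pa), 0, pa) + ifelse(is.na(ma), 0, ma)
  hi <- ifelse(is.na(pa), 1, pa) + ifelse(is.na(ma), 1, ma)
  gc >= lo & gc <= hi
}

#' Sequence-panel quality control
#'
#' Applies the fine-mapping VCF filters in their stated order, each rule
#' counted on the set surviving the previous ones: (1) variants with a
#' missing call rate above `var_missing`; (2) variants with minor allele
#' frequency below `maf`; (3) samples with a missing call rate above
#' `sample_missing`; (4) samples, then variants, with a Mendelian error
#' rate above `mendel` (computed from the panel's family links). All
#' missingness/Mendelian bounds are strict (`>`), the MAF bound keeps
#' `maf` itself out (`<`).
#'
#' @param panel a `seq_panel`.
#' @param var_missing,maf,sample_missing,mendel thresholds (defaults 0.1,
#'   0.01, 0.1, 0.02).
#' @return List with `panel` (filtered) and `report` (`data.frame` of
#'   per-rule removal counts; conserved against the input).
#' @export
vcf_qc <- function(panel, var_missing = 0.1, maf = 0.01,
                   sample_missing = 0.1, mendel = 0.02) {
  stopifnot(var_missing >= 0, var_missing <= 1, maf >= 0, maf <= 0.5)
  geno <- panel$geno
  n_var0 <- ncol(geno)
  n_samp0 <- nrow(geno)

  vm <- colMeans(is.na(geno))
  keep_v <- vm <= var_missing
  n_var_miss <- sum(!keep_v)
  geno <- geno[, keep_v, drop = FALSE]
  variants <- panel$variants[keep_v, , drop = FALSE]

  p <- colMeans(geno, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  keep_v <- !is.na(mafs) & mafs >= maf
  n_maf <- sum(!keep_v)
  geno <- geno[, keep_v, drop = FALSE]
  variants <- variants[keep_v, , drop = FALSE]

  sm <- rowMeans(is.na(geno))
  keep_s <- sm <= sample_missing
  n_samp_miss <- sum(!keep_s)
  geno <- geno[keep_s, , drop = FALSE]

  prune_families <- function(fam, ids) {
    if (is.null(fam) || nrow(fam) == 0) return(fam)
    fam$sire[!fam$sire %in% ids] <- NA
    fam$dam[!fam$dam %in% ids] <- NA
    fam[fam$child %in% ids & (!is.na(fam$sire) | !is.na(fam$dam)), ,
      drop = FALSE
    ]
  }
  tmp <- panel
  tmp$geno <- geno
  tmp$variants <- variants
  tmp$samples <- panel$samples[keep_s, , drop = FALSE]
  tmp$families <- prune_families(panel$families, rownames(geno))
  mend <- mendelian_error_rate(tmp)
  bad_s <- mend$per_sample$sample[mend$per_sample$rate > mendel]
  n_mend_s <- length(bad_s)
  keep_s2 <- !rownames(geno) %in% bad_s
  geno <- geno[keep_s2, , drop = FALSE]
  tmp$geno <- geno
  tmp$samples <- tmp$samples[keep_s2, , drop = FALSE]
  tmp$families <- prune_families(tmp$families, rownames(geno))
  mend2 <- mendelian_error_rate(tmp)
  bad_v <- mend2$per_variant$rate > mendel
  n_mend_v <- sum(bad_v)
  tmp$geno <- geno[, !bad_v, drop = FALSE]
  tmp$variants <- variants[!bad_v, , drop = FALSE]

  report <- data.frame(
    rule = c(
      "input_variants", "variant_missingness", "variant_maf",
      "mendelian_variants", "retained_variants",
      "input_samples", "sample_missingness", "mendelian_samples",
      "retained_samples"
    ),
    n = c(
      n_var0, n_var_miss, n_maf, n_mend_v, ncol(tmp$geno),
      n_samp0, n_samp_miss, n_mend_s, nrow(tmp$geno)
    )
  )
  stopifnot(
    n_var_miss + n_maf + n_mend_v + ncol(tmp$geno) == n_var0,
    n_samp_miss + n_mend_s + nrow(tmp$geno) == n_samp0
  )
  list(panel = tmp, report = report)
}

#' LD screen of sequence variants against a haplotype diplotype
#'
#' Squared Pearson correlation between the focal haplotype's diplotype
#' dosage (0/1/2 copies) and every variant's alt-allele dosage, over the
#' samples non-missing for both (pairwise complete). Variants inside the
#' window with `r2` at or above the floor are returned, sorted by `r2`
#' descending. `r2` is invariant to allele relabeling of either coding.
#'
#' @param diplotype named dosage vector (names = sample ids).
#' @param panel a `seq_panel`.
#' @param window optional `c(start, end)` bp bounds restricting the screen.
#' @param r2_floor minimum `r2` (default 0.7).
#' @return `data.frame` with `variant`, `chrom`, `pos`, `alleles`, `maf`,
#'   `r2`; zero-variance variants are skipped and listed in
#'   `attr(, "skipped")`.
#' @export
haplotype_variant_ld <- function(diplotype, panel, window = NULL,
                                 r2_floor = 0.7) {
  ids <- intersect(names(diplotype), rownames(panel$geno))
  if (length(ids) == 0) stop_twinqtl("no overlapping samples")
  d <- as.numeric(diplotype[ids])
  geno <- panel$geno[ids, , drop = FALSE]
  variants <- panel$variants
  sel <- rep(TRUE, nrow(variants))
  if (!is.null(window)) {
    sel <- variants$pos >= window[1] & variants$pos <= window[2]
  }
  r2 <- maf <- rep(NA_real_, nrow(variants))
  skipped <- character(0)
  for (j in which(sel)) {
    g <- geno[, j]
    ok <- !is.na(g)
    if (sum(ok) < 3 || var(g[ok]) == 0 || var(d[ok]) == 0) {
      skipped <- c(skipped, colnames(geno)[j])
      next
    }
    r2[j] <- cor(d[ok], g[ok])^2
    pj <- mean(g[ok]) / 2
    maf[j] <- min(pj, 1 - pj)
  }
  keep <- !is.na(r2) & r2 >= r2_floor
  out <- data.frame(
    variant = colnames(geno)[keep],
    chrom = variants$chrom[keep], pos = variants$pos[keep],
    alleles = paste0(variants$ref[keep], ">", variants$alt[keep]),
    maf = maf[keep], r2 = r2[keep]
  )
  out <- out[order(-out$r2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Per-breed alt-allele frequencies of a variant
#'
#' Frequency of the alt allele over non-missing calls, for every breed with
#' at least `min_records` genotyped samples (inclusive bound).
#'
#' @param panel a `seq_panel` with breed labels in `panel$samples`.
#' @param variant variant column name or index.
#' @param min_records minimum genotyped samples per breed (default 50).
#' @return `data.frame` with `breed`, `n`, `freq`, sorted by frequency.
#' @export
breed_frequencies <- function(panel, variant, min_records = 50) {
  g <- panel$geno[, variant]
  breed <- panel$samples$breed[match(rownames(panel$geno), panel$samples$id)]
  ok <- !is.na(g)
  tab <- table(breed[ok])
  keep <- names(tab)[tab >= min_records]
  out <- do.call(rbind, lapply(keep, function(b) {
    sel <- ok & breed == b
    data.frame(breed = b, n = sum(sel), freq = mean(g[sel]) / 2)
  }))
  if (is.null(out)) {
    return(data.frame(breed = character(0), n = integer(0), freq = numeric(0)))
  }
  out[order(-out$freq), , drop = FALSE]
}
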