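#' De-regress estimated breeding values
#'
#' Removes the parent-average contribution and the BLUP shrinkage from EBVs
#' so they can be used as pseudo-phenotypes in association analysis. For an
#' animal with at least one known parent the parent-average / individual
#' two-equation information system of Garrick-style de-regression is solved:
#' the parent average `gPA` is the mean of the parental EBVs (an absent
#' parent contributes EBV 0 and reliability 0), its reliability is
#' `r2PA = (r2_sire + r2_dam) / 4`, the effective information contents
#' `Z'Z_PA` and `Z'Z_i` follow from the two reliabilities, and the
#' de-regressed proof is the individual equation's right-hand side divided
#' by its own information. For a founder (both parents unknown) the system
#' collapses to the classical single-animal de-regression `EBV / r2`. Each
#' record also receives the scalar weight
#' `w = (1 - h2) / ((c + (1 - r2_dereg) / r2_dereg) * h2)`
#' used by weighted genomic analyses, where `c` is the fraction of genetic
#' variance not captured by markers.
#'
#' Animals whose reliability does not exceed their parent-average
#' reliability carry no own information; they are excluded and reported.
#'
#' @param ebv EBV `data.frame` with `animal`, `trait`, `ebv`, `reliability`.
#' @param pedigree pedigree (`id`, `sire`, `dam`).
#' @param h2 heritability of the trait on the response scale (used for the
#'   shrinkage factor `lambda = (1 - h2) / h2`).
#' @param c fraction of genetic variance not accounted for by markers
#'   (default 0.5).
#' @return A `data.frame` of class `deregressed`: `animal`, `trait`,
#'   `deregressed`, `weight`, `reliability` (source), `r2_dereg`, `r2_pa`,
#'   `pa_value` (parent-average EBV). Excluded animals are listed in
#'   `attr(, "excluded")`.
#' @export
deregress_ebv <- function(ebv, pedigree, h2, c = 0.5) {
  stopifnot(h2 > 0, h2 < 1, c >= 0, c < 1)
  if (any(ebv$reliability <= 0 | ebv$reliability >= 1)) {
    stop_twinqtl("reliabilities must be in (0, 1) for de-regression")
  }
  lambda <- (1 - h2) / h2
  row <- match(ebv$animal, pedigree$id)
  if (anyNA(row)) stop_twinqtl("EBV animals missing from pedigree")

  out_list <- list()
  excluded <- list()
  for (tr in unique(ebv$trait)) {
    sel <- which(ebv$trait == tr)
    g <- setNames(ebv$ebv[sel], ebv$animal[sel])
    r2 <- setNames(ebv$reliability[sel], ebv$animal[sel])
    sire <- pedigree$sire[row[sel]]
    dam <- pedigree$dam[row[sel]]
    g_s <- ifelse(is.na(sire), 0, g[as.character(sire)])
    g_d <- ifelse(is.na(dam), 0, g[as.character(dam)])
    r2_s <- ifelse(is.na(sire), 0, r2[as.character(sire)])
    r2_d <- ifelse(is.na(dam), 0, r2[as.character(dam)])
    g_s[is.na(g_s)] <- 0
    g_d[is.na(g_d)] <- 0
    r2_s[is.na(r2_s)] <- 0
    r2_d[is.na(r2_d)] <- 0
    gPA <- (g_s + g_d) / 2
    r2PA <- pmin((r2_s + r2_d) / 4, 0.49999)

    no_parent <- is.na(sire) & is.na(dam)
    no_info <- unname(r2) <= r2PA & !no_parent

    drp <- r2d <- rep(NA_real_, length(sel))
    # founders: classical single-animal de-regression
    drp[no_parent] <- g[no_parent] / r2[no_parent]
    r2d[no_parent] <- r2[no_parent]
    # two-equation system for animals with parent information
    full <- which(!no_parent & !no_info)
    if (length(full) > 0) {
      alpha <- 1 / (0.5 - r2PA[full])
      delta <- (0.5 - r2PA[full]) / (1 - r2[full])
      ZpZpa <- lambda * (0.5 * alpha - 4) +
        0.5 * lambda * sqrt(alpha^2 + 16 / delta)
      ZpZi <- delta * ZpZpa + 2 * lambda * (2 * delta - 1)
      rhs_i <- -2 * lambda * gPA[full] + (ZpZi + 2 * lambda) * g[full]
      drp[full] <- rhs_i / ZpZi
      r2d[full] <- ZpZi / (ZpZi + lambda)
    }

    keep <- !no_info
    w <- (1 - h2) / ((c + (1 - r2d) / r2d) * h2)
    out_list[[tr]] <- data.frame(
      animal = ebv$animal[sel][keep], trait = tr,
      deregressed = drp[keep], weight = w[keep],
      reliability = r2[keep], r2_dereg = r2d[keep],
      r2_pa = r2PA[keep], pa_value = gPA[keep]
    )
    if (any(no_info)) {
      excluded[[tr]] <- data.frame(
        animal = ebv$animal[sel][no_info], trait = tr,
        reliability = unname(r2[no_info]), r2_pa = r2PA[no_info]
      )
    }
  }
  out <- do.call(rbind, out_list)
  rownames(out) <- NULL
  class(out) <- c("deregressed", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else NULL
  attr(out, "h2") <- h2
  attr(out, "c") <- c
  out
}

#' Reliability filter for de-regressed proofs
#'
#' Keeps records whose source EBV reliability is at least `min_reliability`
#' (inclusive bound).
#'
#' @param dereg output of [deregress_ebv()] (any `data.frame` with
#'   `reliability` and `trait`).
#' @param min_reliability threshold, default 0.35.
#' @return The retained subset; per-trait retained/removed counts in
#'   `attr(, "counts")`.
#' @export
filter_reliability <- function(dereg, min_reliability = 0.35) {
  keep <- dereg$reliability >= min_reliability
  counts <- aggregate(
    keep, by = list(trait = dereg$trait),
    FUN = function(k) c(retained = sum(k), removed = sum(!k))
  )
  out <- dereg[keep, , drop = FALSE]
  attr(out, "counts") <- counts
  out
}
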