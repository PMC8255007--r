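#' Simulate birth records from the direct-maternal animal model
#'
#' Every pedigree animal with a known dam generates one birth record. The
#' latent record value is the sum of the fixed part (parity, season, sexed
#' semen, age-of-dam slope and intercept), a random herd-year effect, the
#' calf's direct breeding value, the dam's maternal breeding value, the
#' planted QTL contribution (the configured effect times the dam's diplotype
#' dosage of the focal haplotype, added to her maternal value), and a
#' residual. Direct and maternal breeding values are sampled jointly down
#' the pedigree with the configured direct-maternal covariance and the exact
#' Mendelian-sampling variance (inbreeding-adjusted).
#'
#' In `"gaussian"` mode the latent value is emitted as the (continuous)
#' 1/2-coded response, so the data-generating process is exactly the linear
#' mixed model fitted downstream. In `"binary"` mode the latent value is
#' thresholded: records above the threshold get multiple-birth code 2,
#' others code 1. If no explicit threshold is configured it is calibrated to
#' the target prevalence from the realized latent distribution.
#'
#' @param pedigree pedigree from [simulate_pedigree()].
#' @param genotypes optional [simulate_genotypes()] output; required when the
#'   configuration plants a QTL.
#' @param config the [sim_config()] object.
#' @return A `data.frame` of class `birth_records` with columns `calf`,
#'   `dam`, `herd`, `year`, `season`, `parity`, `sexed_semen`, `age_months`,
#'   `embryo_transfer` and `code`. Simulation ground truth (breeding values,
#'   herd-year effects, threshold) is stored in `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_pedigree(pedigree)
  vc <- config$variance_components
  if (!is.null(config$qtl) && is.null(genotypes)) {
    stop_twinqtl("a QTL is configured; phased genotypes are required")
  }
  with_seed(child_seed(config$seed, 3), {
    n <- nrow(pedigree)
    idx_s <- match(pedigree$sire, pedigree$id)
    idx_d <- match(pedigree$dam, pedigree$id)

    # joint direct/maternal breeding values by recursive gene-flow sampling
    G0 <- matrix(
      c(vc$direct, vc$covariance, vc$covariance, vc$maternal), 2, 2
    )
    L <- if (all(G0 == 0)) {
      matrix(0, 2, 2)
    } else {
      t(chol(G0 + diag(1e-12 * max(diag(G0)), 2)))
    }
    Fc <- inbreeding_coefficients(pedigree)
    z <- matrix(rnorm(2 * n), n, 2)
    bv <- matrix(0, n, 2, dimnames = list(pedigree$id, c("direct", "maternal")))
    for (i in seq_len(n)) {
      pa <- c(0, 0)
      phi <- 1
      if (!is.na(idx_s[i])) {
        pa <- pa + 0.5 * bv[idx_s[i], ]
        phi <- phi - 0.25 * (1 + Fc[idx_s[i]])
      }
      if (!is.na(idx_d[i])) {
        pa <- pa + 0.5 * bv[idx_d[i], ]
        phi <- phi - 0.25 * (1 + Fc[idx_d[i]])
      }
      bv[i, ] <- pa + sqrt(max(phi, 0)) * as.numeric(L %*% z[i, ])
    }

    rec_rows <- which(!is.na(idx_d))
    if (length(rec_rows) == 0) stop_twinqtl("pedigree has no calves with dams")
    calf <- pedigree$id[rec_rows]
    dam <- pedigree$dam[rec_rows]
    year <- pedigree$birth_year[rec_rows]
    herd <- pedigree$herd[rec_rows]
    ord <- order(year, calf)
    rec_rows <- rec_rows[ord]
    calf <- calf[ord]; dam <- dam[ord]; year <- year[ord]; herd <- herd[ord]

    # parity: 1 + number of earlier calvings of the dam
    parity <- stats::ave(seq_along(dam), dam, FUN = seq_along)
    dam_row <- match(dam, pedigree$id)
    age_months <- (year - pedigree$birth_year[dam_row]) * 12 +
      (pedigree$birth_month[rec_rows] - pedigree$birth_month[dam_row])
    season <- season_from_month(pedigree$birth_month[rec_rows])
    sexed <- ifelse(runif(length(calf)) < config$sexed_semen_rate, "yes", "no")
    et <- runif(length(calf)) < config$embryo_transfer_rate

    hy_key <- paste(herd, year, sep = ":")
    hy_levels <- sort(unique(hy_key))
    hy_eff <- setNames(rnorm(length(hy_levels), 0, sqrt(vc$herd_year)), hy_levels)

    fe <- config$fixed_effects
    latent <- fe$intercept +
      fe$parity[pmin(parity, 5)] +
      unname(fe$sexed[sexed]) +
      unname(fe$season[season]) +
      fe$age_slope * age_months +
      hy_eff[hy_key] +
      bv[rec_rows, "direct"] +
      bv[dam_row, "maternal"] +
      rnorm(length(calf), 0, sqrt(vc$residual))

    if (!is.null(config$qtl)) {
      dip <- qtl_diplotype(genotypes)
      latent <- latent + config$qtl$effect * unname(dip[as.character(dam)])
    }

    if (config$phenotype_mode == "binary") {
      thr <- config$binary_threshold %||%
        unname(quantile(latent, 1 - config$prevalence, type = 8))
      code <- ifelse(latent > thr, 2, 1)
    } else {
      thr <- NA_real_
      code <- latent
    }

    records <- data.frame(
      calf = calf, dam = dam, herd = herd, year = year,
      season = season, parity = parity, sexed_semen = sexed,
      age_months = as.numeric(age_months), embryo_transfer = et,
      code = as.numeric(code)
    )
    class(records) <- c("birth_records", "data.frame")
    attr(records, "truth") <- list(
      bv = bv, herd_year = hy_eff, threshold = thr, latent = latent,
      inbreeding = Fc, seed = config$seed
    )
    records
  })
}
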