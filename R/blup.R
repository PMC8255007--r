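#' Solve the mixed-model equations (BLUP breeding values)
#'
#' Solves Henderson's mixed-model equations at fixed variance components for
#' the fixed effects, the herd-year effects, and the direct (`mbd`) and
#' maternal (`mbm`) breeding values of every pedigree animal. The genetic
#' block uses the inverse of the 2x2 direct-maternal covariance matrix
#' Kronecker the inverse numerator relationship matrix, so animals without
#' records are predicted through the pedigree (an unconnected animal gets
#' the population mean, EBV 0). Prediction-error variances are the genetic
#' diagonal entries of the inverse coefficient matrix, computed by dense
#' inversion at desk scale.
#'
#' @param design a [build_model_design()] object.
#' @param vc [variance_components()] at which to solve.
#' @param pev compute prediction-error variances (`TRUE`, `FALSE`); dense
#'   inversion is refused above `pev_limit` equations.
#' @param pev_limit largest system size for dense PEV inversion.
#' @return A list of class `blup_fit`: `fixed` (named vector), `herd_year`
#'   (named vector), `ebv` (`data.frame` with `animal`, `trait`
#'   (`mbd`/`mbm`), `ebv`, and `pev` when requested), and `mme` (the
#'   coefficient matrix, right-hand side and solution, for auditing).
#' @export
blup_solve <- function(design, vc, pev = TRUE, pev_limit = 8000) {
  stopifnot(inherits(design, "model_design"), inherits(vc, "variance_components"))
  mm <- mme_build(design, vc)
  ch <- Matrix::Cholesky(mm$C, LDL = FALSE, super = TRUE)
  sol <- as.numeric(Matrix::solve(ch, mm$rhs, system = "A"))
  blocks <- mme_split(sol, mm$p, mm$qh, mm$nA)
  ids <- design$animal_ids
  ebv <- data.frame(
    animal = rep(ids, 2),
    trait = rep(c("mbd", "mbm"), each = mm$nA),
    ebv = c(blocks$a, blocks$m)
  )
  if (isTRUE(pev)) {
    n_eq <- nrow(mm$C)
    if (n_eq > pev_limit) {
      stop_twinqtl(
        "dense PEV inversion refused for ", n_eq, " equations (limit ",
        pev_limit, "); call with pev = FALSE or raise pev_limit"
      )
    }
    Cinv_diag <- diag(solve(as.matrix(mm$C)))
    ebv$pev <- c(
      Cinv_diag[mm$p + mm$qh + seq_len(mm$nA)],
      Cinv_diag[mm$p + mm$qh + mm$nA + seq_len(mm$nA)]
    )
  }
  structure(
    list(
      fixed = setNames(blocks$beta, colnames(design$X)),
      herd_year = setNames(blocks$h, colnames(design$W)),
      ebv = ebv,
      mme = list(C = mm$C, rhs = mm$rhs, solution = sol)
    ),
    class = "blup_fit"
  )
}

#' Reliability of breeding values
#'
#' Squared accuracy `r2 = 1 - PEV / sigma2_g`, where `sigma2_g` is the
#' genetic variance of the corresponding effect (direct variance for trait
#' `mbd`, maternal variance for `mbm`), clamped into `[0, 1]`.
#'
#' @param ebv an EBV `data.frame` with `trait` and `pev` columns (from
#'   [blup_solve()] with `pev = TRUE`).
#' @param vc the [variance_components()] used in the evaluation.
#' @return The input with a `reliability` column added.
#' @export
reliability <- function(ebv, vc) {
  if (is.null(ebv$pev)) stop_twinqtl("ebv table carries no PEV column")
  if (any(ebv$pev < 0)) stop_twinqtl("negative PEV")
  s2g <- ifelse(ebv$trait == "mbd", vc$direct, vc$maternal)
  if (any(s2g <= 0)) stop_twinqtl("genetic variance is zero for a trait")
  ebv$reliability <- pmin(pmax(1 - ebv$pev / s2g, 0), 1)
  ebv
}

#' Standardize breeding values to a base population
#'
#' Applies the affine transform that gives the base-animal group a mean of
#' `target_mean` (default 100) and a standard deviation of `target_sd`
#' (default 12), and applies the same transform to all animals. The default
#' base group are the 8- to 10-year-old sires (males with birth year in
#' `[eval_year - 10, eval_year - 8]`) with a breed fraction of at least 7/8
#' for the base breed.
#'
#' @param ebv EBV `data.frame` (`animal`, `trait`, `ebv`).
#' @param pedigree pedigree with `sex`, `birth_year` and breed fraction
#'   columns.
#' @param eval_year evaluation year; defaults to the maximum birth year.
#' @param base_breed breed label whose fraction defines base animals
#'   (column `breed_<base_breed>`); `NULL` disables the breed rule.
#' @param min_fraction minimum breed fraction of base animals (default 7/8).
#' @param target_mean,target_sd mean and SD of the base group after
#'   standardization.
#' @return The input with an `ebv_std` column; the transform (per trait) is
#'   in `attr(, "transform")`.
#' @export
standardize_ebv <- function(ebv, pedigree, eval_year = NULL,
                            base_breed = "HOL", min_fraction = 7 / 8,
                            target_mean = 100, target_sd = 12) {
  eval_year <- eval_year %||% max(pedigree$birth_year)
  row <- match(ebv$animal, pedigree$id)
  if (anyNA(row)) stop_twinqtl("EBV animals missing from pedigree")
  in_base <- pedigree$sex[row] == "M" &
    pedigree$birth_year[row] >= eval_year - 10 &
    pedigree$birth_year[row] <= eval_year - 8
  if (!is.null(base_breed)) {
    col <- paste0("breed_", base_breed)
    if (col %in% names(pedigree)) {
      in_base <- in_base & pedigree[[col]][row] >= min_fraction
    }
  }
  ebv$ebv_std <- NA_real_
  transforms <- list()
  for (tr in unique(ebv$trait)) {
    sel <- ebv$trait == tr
    base <- sel & in_base
    if (sum(base) < 2) {
      stop_twinqtl("base group for trait ", tr, " has fewer than 2 animals")
    }
    mu <- mean(ebv$ebv[base])
    s <- sd(ebv$ebv[base])
    if (s == 0) stop_twinqtl("base group for trait ", tr, " has zero SD")
    ebv$ebv_std[sel] <- target_mean + target_sd * (ebv$ebv[sel] - mu) / s
    transforms[[tr]] <- c(base_mean = mu, base_sd = s, n_base = sum(base))
  }
  attr(ebv, "transform") <- transforms
  ebv
}

#' Genetic trend by birth year
#'
#' Mean (and SD) of standardized breeding values per birth year and trait —
#' the usual summary used to judge whether a trait has been under selection.
#'
#' @param ebv EBV `data.frame` with `ebv_std` (from [standardize_ebv()]).
#' @param pedigree pedigree with `birth_year`.
#' @param years optional integer vector of years to report (missing years
#'   get `n = 0` rows).
#' @return `data.frame` with `trait`, `year`, `n`, `mean`, `sd`.
#' @export
genetic_trend <- function(ebv, pedigree, years = NULL) {
  if (is.null(ebv$ebv_std)) stop_twinqtl("run standardize_ebv() first")
  year <- pedigree$birth_year[match(ebv$animal, pedigree$id)]
  years <- years %||% seq(min(year), max(year))
  out <- expand.grid(
    trait = unique(ebv$trait), year = years,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out$n <- 0L
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (k in seq_len(nrow(out))) {
    sel <- ebv$trait == out$trait[k] & year == out$year[k]
    out$n[k] <- sum(sel)
    if (out$n[k] > 0) {
      out$mean[k] <- mean(ebv$ebv_std[sel])
      out$sd[k] <- sd(ebv$ebv_std[sel])
    }
  }
  out[order(out$trait, out$year), ]
}
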