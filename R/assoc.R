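#' VanRaden genomic relationship matrix
#'
#' Method-1 genomic relationship matrix: dosages centered by twice the
#' allele frequency, cross-product scaled by `2 * sum(p * (1 - p))`.
#' Monomorphic markers and markers below the minor-allele-frequency floor
#' are excluded and reported.
#'
#' @param dosages animals x markers matrix of alt-allele counts (0/1/2).
#' @param maf_floor minimum minor allele frequency (default 0.01).
#' @return The n x n relationship matrix; used marker names in
#'   `attr(, "markers_used")`, excluded ones in `attr(, "markers_excluded")`.
#' @export
build_grm <- function(dosages, maf_floor = 0.01) {
  if (nrow(dosages) < 2 || ncol(dosages) < 1) {
    stop_twinqtl("need at least 2 animals and 1 marker")
  }
  p <- colMeans(dosages) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_floor & maf > 0
  if (!any(keep)) stop_twinqtl("all markers monomorphic or below the MAF floor")
  Z <- sweep(dosages[, keep, drop = FALSE], 2, 2 * p[keep])
  G <- tcrossprod(Z) / (2 * sum(p[keep] * (1 - p[keep])))
  attr(G, "markers_used") <- colnames(dosages)[keep]
  attr(G, "markers_excluded") <- colnames(dosages)[!keep]
  G
}

#' Pedigree-based breed-proportion filter
#'
#' Returns the animals whose pedigree-based gene proportion of the given
#' breed is strictly greater than `min_fraction`.
#'
#' @param pedigree pedigree with a `breed_<breed>` column.
#' @param min_fraction threshold (strict inequality), default 0.6.
#' @param breed breed label, default `"HOL"`.
#' @return Integer vector of retained animal ids; count in `attr(, "n")`.
#' @export
breed_proportion_filter <- function(pedigree, min_fraction = 0.6, breed = "HOL") {
  col <- paste0("breed_", breed)
  if (!col %in% names(pedigree)) {
    stop_twinqtl("pedigree has no breed fraction column ", col)
  }
  ids <- pedigree$id[pedigree[[col]] > min_fraction]
  attr(ids, "n") <- length(ids)
  ids
}

#' Fit the polygenic null model of the single-SNP scan
#'
#' REML fit of `y = mu + a + e`, `a ~ N(0, G sigma2_a)`, on the de-regressed
#' response, via the spectral decomposition of the genomic relationship
#' matrix and a one-dimensional profile of the restricted likelihood over
#' the variance ratio. Deterministic.
#'
#' @param y de-regressed response, one value per animal (names optional).
#' @param grm genomic relationship matrix for the same animals.
#' @param bend small ridge added to non-positive eigenvalues (tolerance for
#'   near-singular matrices).
#' @return Object of class `null_model`: `sigma2_a`, `sigma2_e`, `mu`,
#'   `loglik`, plus the rotated quantities reused by the scans (`U`,
#'   eigenvalues `d`, rotated response and intercept).
#' @export
fit_null_model <- function(y, grm, bend = 1e-8) {
  n <- length(y)
  stopifnot(nrow(grm) == n, ncol(grm) == n)
  eg <- eigen(grm, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-4 * max(abs(d))) {
    stop_twinqtl("relationship matrix is not positive semi-definite")
  }
  d <- pmax(d, bend)
  U <- eg$vectors
  ys <- as.numeric(crossprod(U, y))
  xs <- as.numeric(crossprod(U, rep(1, n)))

  # profile restricted log-likelihood of log(delta), delta = s2e/s2a
  neg_rll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    xwx <- sum(w * xs^2)
    bhat <- sum(w * xs * ys) / xwx
    r <- ys - xs * bhat
    rss <- sum(w * r^2)
    # s2a profiled out: (n-1) log(rss) + sum log(d+delta) + log(xwx)
    (n - 1) * log(rss) + sum(log(d + delta)) + log(xwx)
  }
  opt <- optimize(neg_rll, c(-12, 12))
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  xwx <- sum(w * xs^2)
  mu <- sum(w * xs * ys) / xwx
  rss <- sum(w * (ys - xs * mu)^2)
  s2a <- rss / (n - 1)
  s2e <- delta * s2a
  structure(
    list(
      sigma2_a = s2a, sigma2_e = s2e, mu = mu,
      loglik = -0.5 * (opt$objective + (n - 1) * (1 - log(n - 1))),
      U = U, d = d, delta = delta, ys = ys, xs = xs, n = n
    ),
    class = "null_model"
  )
}

# Shared GLS core: test dosage columns against the null-model rotation.
# Returns beta, se, p for each column of `gmat` (animals x tests).
gls_scan_core <- function(gmat, null) {
  w <- 1 / (null$d + null$delta)
  gs <- crossprod(null$U, gmat) # rotated dosages
  xs <- null$xs
  ys <- null$ys
  xwx <- sum(w * xs^2)
  xwy <- sum(w * xs * ys)
  gwg <- colSums(w * gs^2)
  gwx <- as.numeric(crossprod(gs, w * xs))
  gwy <- as.numeric(crossprod(gs, w * ys))
  # 2x2 GLS of (intercept, dosage) by block elimination; variance
  # parameters stay fixed at the null fit (single-rotation EMMAX)
  det2 <- xwx * gwg - gwx^2
  beta <- (xwx * gwy - gwx * xwy) / det2
  se <- sqrt(pmax(null$sigma2_a * xwx / det2, 0))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  list(beta = beta, se = se, p = p)
}

#' Single-SNP mixed-model association scan
#'
#' EMMAX-style genome scan on the de-regressed response: the polygenic and
#' residual variances are fixed at the null fit, every marker is tested by
#' generalized least squares in the eigen-rotated space (a single rotation,
#' no per-marker REML), and the Wald p-value is two-sided. The variance
#' explained by a marker is reported as `2 p (1 - p) beta^2`.
#'
#' @param y de-regressed response.
#' @param dosages animals x markers dosage matrix (0/1/2, alt-allele count).
#' @param null [fit_null_model()] output on the same animals.
#' @param map optional marker map (`chrom`, `pos`, `id`, `ref`, `alt`) in
#'   column order of `dosages`.
#' @return `data.frame` with `marker`, `chrom`, `pos`, `alleles`, `freq`,
#'   `beta`, `se`, `variance`, `p`; monomorphic markers get `NA` effects and
#'   a `flagged` entry.
#' @export
single_snp_scan <- function(y, dosages, null, map = NULL) {
  stopifnot(inherits(null, "null_model"), nrow(dosages) == null$n)
  p_freq <- colMeans(dosages) / 2
  poly <- p_freq > 0 & p_freq < 1
  res <- list(
    beta = rep(NA_real_, ncol(dosages)), se = rep(NA_real_, ncol(dosages)),
    p = rep(NA_real_, ncol(dosages))
  )
  if (any(poly)) {
    core <- gls_scan_core(dosages[, poly, drop = FALSE], null)
    res$beta[poly] <- core$beta
    res$se[poly] <- core$se
    res$p[poly] <- core$p
  }
  out <- data.frame(
    marker = colnames(dosages) %||% paste0("m", seq_len(ncol(dosages))),
    chrom = if (!is.null(map)) map$chrom else NA,
    pos = if (!is.null(map)) map$pos else NA,
    alleles = if (!is.null(map)) paste0(map$ref, "/", map$alt) else NA,
    freq = p_freq,
    beta = res$beta, se = res$se,
    variance = 2 * p_freq * (1 - p_freq) * res$beta^2,
    p = res$p,
    flagged = !poly
  )
  rownames(out) <- NULL
  out
}

#' Bonferroni-significant markers
#'
#' Keeps results with `p <= alpha / n_tests` and reports the threshold.
#'
#' @param results a `data.frame` with a `p` column.
#' @param n_tests number of tests in the family (at least the number of
#'   rows considered).
#' @param alpha family-wise error level in (0, 1).
#' @return The significant subset; the threshold in `attr(, "threshold")`.
#' @export
bonferroni_significant <- function(results, n_tests, alpha) {
  if (alpha <= 0 || alpha >= 1) stop_twinqtl("alpha must be in (0, 1)")
  if (n_tests < sum(!is.na(results$p))) {
    stop_twinqtl("n_tests is smaller than the number of results")
  }
  thr <- alpha / n_tests
  out <- results[!is.na(results$p) & results$p <= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}
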