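#' BayesB chain configuration
#'
#' @param pi prior proportion of zero-effect loci (default 0.989).
#' @param n_iter,burnin,thin chain length, burn-in, thinning.
#' @param nu prior degrees of freedom of the locus-variance scaled inverse
#'   chi-square (default 4.2).
#' @param genetic_var_share share of the response variance assumed genetic
#'   when deriving the prior scale (default 0.5).
#' @param mh_cycles Metropolis-Hastings proposals per locus and iteration
#'   for the locus variance.
#' @param seed chain seed.
#' @param window_mode `"megabase"` (1-Mb windows, default) or `"snp_count"`.
#' @param window_size window size: bp in megabase mode (default 1e6), SNPs
#'   in snp_count mode (default 25).
#' @return A validated list of class `bayesb_config`.
#' @export
bayesb_config <- function(pi = 0.989, n_iter = 21000, burnin = 1000,
                          thin = 10, nu = 4.2, genetic_var_share = 0.5,
                          mh_cycles = 10, seed = 1,
                          window_mode = c("megabase", "snp_count"),
                          window_size = NULL) {
  window_mode <- match.arg(window_mode)
  if (pi <= 0 || pi >= 1) stop_twinqtl("pi must be in (0, 1)")
  if (n_iter <= burnin) stop_twinqtl("chain must be longer than the burn-in")
  window_size <- window_size %||% if (window_mode == "megabase") 1e6 else 25
  structure(
    list(
      pi = pi, n_iter = n_iter, burnin = burnin, thin = thin, nu = nu,
      genetic_var_share = genetic_var_share, mh_cycles = mh_cycles,
      seed = seed, window_mode = window_mode, window_size = window_size
    ),
    class = "bayesb_config"
  )
}

#' BayesB whole-genome regression sampler
#'
#' Gibbs chain over all markers simultaneously: each locus carries a
#' point-mass-at-zero / scaled-inverse-chi-square mixture prior on its
#' effect variance (prior inclusion probability `1 - pi`), sampled by a
#' per-locus Metropolis-Hastings step with the effect integrated out;
#' included effects are drawn from their conditional normal and the
#' residual variance from its conditional each iteration. The prior scale
#' is derived from the assumed genetic variance
#' (`genetic_var_share * var(y)`), `pi` and the marker heterozygosity.
#'
#' @param y de-regressed response.
#' @param dosages animals x markers dosage matrix (0/1/2).
#' @param config a [bayesb_config()].
#' @return Object of class `bayesb_fit`: thinned effect samples (`beta`,
#'   samples x markers), residual-variance and mean samples, per-marker
#'   posterior inclusion frequencies, the centered dosage matrix, and the
#'   configuration.
#' @export
bayesb_sample <- function(y, dosages, config = bayesb_config()) {
  stopifnot(inherits(config, "bayesb_config"), nrow(dosages) == length(y))
  if (!all(is.finite(y))) stop_twinqtl("response contains non-finite values")
  p_freq <- colMeans(dosages) / 2
  sum2pq <- sum(2 * p_freq * (1 - p_freq))
  if (sum2pq <= 0) stop_twinqtl("all markers monomorphic")
  var_g <- config$genetic_var_share * var(y)
  # prior scale so that E[locus variance] * expected included heterozygosity
  # matches the assumed genetic variance
  s_beta <- var_g * (config$nu - 2) /
    (config$nu * (1 - config$pi) * sum2pq)
  Xc <- sweep(dosages, 2, 2 * p_freq)
  res <- with_seed(config$seed, {
    .bayesb_mcmc(
      Xc, y, config$pi, as.integer(config$n_iter),
      as.integer(config$burnin), as.integer(config$thin),
      config$nu, s_beta, as.integer(config$mh_cycles)
    )
  })
  colnames(res$beta) <- colnames(dosages)
  structure(
    list(
      beta = res$beta, ve = res$ve, mu = res$mu,
      inclusion = setNames(as.numeric(res$inclusion), colnames(dosages)),
      X = Xc, config = config
    ),
    class = "bayesb_fit"
  )
}

# Window index per marker under the configured window mode.
window_index <- function(map, config) {
  if (config$window_mode == "megabase") {
    key <- paste(map$chrom, (map$pos - 1) %/% config$window_size, sep = ":")
  } else {
    # per-chromosome blocks of window_size consecutive SNPs
    key <- character(nrow(map))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      key[idx] <- paste(ch, (seq_along(idx) - 1) %/% config$window_size,
        sep = ":"
      )
    }
  }
  key
}

#' Per-window genetic-variance partition of a BayesB chain
#'
#' For every stored iteration, the genetic variance of a window is the
#' variance over animals of the window's genomic value (its markers'
#' dosages times their sampled effects); the window's proportion is that
#' variance divided by the sum over windows in the same iteration, so
#' proportions sum to one in every iteration. `p_gt0` is the fraction of
#' iterations in which any marker of the window had a nonzero effect;
#' `p_gt_average` the fraction in which the window's proportion exceeded
#' `1 / n_windows` (the share under an equal split). The table is sorted by
#' posterior-mean proportion, with the cumulative proportion accumulated in
#' that order.
#'
#' @param fit a [bayesb_sample()] result.
#' @param map marker map (`chrom`, `pos`) in column order of the fitted
#'   dosages.
#' @return `data.frame` of class `window_variance`: `chrom`, `start`,
#'   `end`, `n_snps`, `prop_var` (posterior mean, %), `cum_prop` (%),
#'   `p_gt0`, `p_gt_average`.
#' @export
window_variance <- function(fit, map) {
  stopifnot(inherits(fit, "bayesb_fit"), nrow(map) == ncol(fit$beta))
  config <- fit$config
  key <- window_index(map, config)
  if (config$window_mode == "megabase") {
    # enumerate every bin up to the last mapped position, so marker-free
    # windows appear with n_snps = 0 and zero variance
    wins <- unlist(lapply(unique(map$chrom), function(ch) {
      paste(ch, 0:((max(map$pos[map$chrom == ch]) - 1) %/% config$window_size),
        sep = ":"
      )
    }))
  } else {
    wins <- unique(key)
  }
  n_win <- length(wins)
  n_samp <- nrow(fit$beta)
  n <- nrow(fit$X)

  var_mat <- matrix(0, n_samp, n_win, dimnames = list(NULL, wins))
  any_mat <- matrix(FALSE, n_samp, n_win)
  for (k in seq_len(n_win)) {
    idx <- which(key == wins[k])
    B <- fit$beta[, idx, drop = FALSE]
    nz <- rowSums(B != 0) > 0
    any_mat[, k] <- nz
    if (any(nz)) {
      U <- fit$X[, idx, drop = FALSE] %*% t(B[nz, , drop = FALSE])
      cm <- colMeans(U)
      var_mat[nz, k] <- (colSums(U^2) - n * cm^2) / (n - 1)
    }
  }
  tot <- rowSums(var_mat)
  prop <- var_mat / ifelse(tot > 0, tot, 1)
  prop[tot == 0, ] <- 0

  out <- data.frame(
    chrom = vapply(strsplit(wins, ":"), `[`, "", 1),
    start = NA_real_, end = NA_real_,
    n_snps = vapply(wins, function(wn) sum(key == wn), 0L),
    prop_var = 100 * colMeans(prop),
    p_gt0 = colMeans(any_mat),
    p_gt_average = colMeans(prop > 1 / n_win)
  )
  for (k in seq_len(n_win)) {
    idx <- which(key == wins[k])
    if (length(idx) > 0) {
      out$start[k] <- min(map$pos[idx])
      out$end[k] <- max(map$pos[idx])
    } else {
      bin <- as.numeric(strsplit(wins[k], ":")[[1]][2])
      out$start[k] <- bin * config$window_size + 1
      out$end[k] <- (bin + 1) * config$window_size
    }
  }
  out <- out[order(-out$prop_var), ]
  out$cum_prop <- cumsum(out$prop_var)
  rownames(out) <- NULL
  class(out) <- c("window_variance", "data.frame")
  attr(out, "n_windows") <- n_win
  out
}

#' Significant BayesB windows
#'
#' A window is called significant at level 5% when `p_gt_average >= 0.95`
#' and at 1% when `p_gt_average >= 0.99` (thresholds configurable via
#' `level`).
#'
#' @param wv a [window_variance()] table.
#' @param level significance level (default 0.05).
#' @return The significant subset of `wv`.
#' @export
significant_windows <- function(wv, level = 0.05) {
  if (nrow(wv) == 0) stop_twinqtl("empty window table")
  wv[wv$p_gt_average >= 1 - level, , drop = FALSE]
}
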