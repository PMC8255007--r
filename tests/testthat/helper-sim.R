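# Shared fixtures and independent oracles for the test suite.

# Small herd configuration used by several module tests.
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_founders = 60, founder_female_frac = 0.75,
    n_generations = 3, offspring_per_generation = 40, n_herds = 3,
    years = 2006:2010, n_chromosomes = 1, snps_per_chromosome = 40,
    chromosome_length = 1e6, qtl = NULL
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Independent dense oracle: tabular (recursive) numerator relationship matrix.
tabular_a <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0
    for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(s[i])) a <- a + 0.5 * A[j, s[i]]
      if (!is.na(d[i])) a <- a + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- a
    }
  }
  A
}

# Independent dense restricted -2 log-likelihood of the animal model.
dense_m2ll <- function(design, vc) {
  X <- design$X
  W <- as.matrix(design$W)
  Zd <- as.matrix(design$Zd)
  Zm <- as.matrix(design$Zm)
  A <- solve(as.matrix(design$a_inverse$Ainv))
  n <- length(design$y)
  V <- vc$herd_year * W %*% t(W) +
    vc$direct * Zd %*% A %*% t(Zd) +
    vc$covariance * (Zd %*% A %*% t(Zm) + Zm %*% A %*% t(Zd)) +
    vc$maternal * Zm %*% A %*% t(Zm) +
    diag(vc$residual, n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  as.numeric(
    determinant(V)$modulus + determinant(XVX)$modulus +
      t(design$y) %*% P %*% design$y
  )
}

# Dense GLS solutions (fixed effects and genetic BLUPs) for oracle checks.
dense_gls <- function(design, vc) {
  X <- design$X
  W <- as.matrix(design$W)
  Zd <- as.matrix(design$Zd)
  Zm <- as.matrix(design$Zm)
  A <- solve(as.matrix(design$a_inverse$Ainv))
  n <- length(design$y)
  V <- vc$herd_year * W %*% t(W) +
    vc$direct * Zd %*% A %*% t(Zd) +
    vc$covariance * (Zd %*% A %*% t(Zm) + Zm %*% A %*% t(Zd)) +
    vc$maternal * Zm %*% A %*% t(Zm) +
    diag(vc$residual, n)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% design$y)
  e <- design$y - X %*% b
  u_a <- (vc$direct * A %*% t(Zd) + vc$covariance * A %*% t(Zm)) %*% Vi %*% e
  u_m <- (vc$covariance * A %*% t(Zd) + vc$maternal * A %*% t(Zm)) %*% Vi %*% e
  list(fixed = as.numeric(b), mbd = as.numeric(u_a), mbm = as.numeric(u_m))
}

# Hand-built phased genotypes object for haplotype tests.
manual_phased <- function(H1, H2, pos = NULL, chrom = 1) {
  m <- ncol(H1)
  pos <- pos %||% seq(1000, by = 1000, length.out = m)
  map <- data.frame(
    chrom = chrom, pos = pos, id = paste0("s", seq_len(m)),
    ref = "A", alt = "C"
  )
  structure(
    list(map = map, H1 = H1, H2 = H2, ids = seq_len(nrow(H1))),
    class = "phased_genotypes"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
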