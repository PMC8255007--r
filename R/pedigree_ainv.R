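# Numerator-relationship machinery: inbreeding by Meuwissen-Luo ancestor
# tracing (compiled), A-inverse by Henderson's rules.

# Topological (parents-first) permutation; errors on cycles.
pedigree_order <- function(pedigree) {
  n <- nrow(pedigree)
  idx_s <- match(pedigree$sire, pedigree$id)
  idx_d <- match(pedigree$dam, pedigree$id)
  pos <- seq_len(n)
  if (!any(idx_s >= pos, na.rm = TRUE) && !any(idx_d >= pos, na.rm = TRUE)) {
    return(pos)
  }
  # Kahn's algorithm on parent -> offspring edges
  indeg <- (!is.na(idx_s)) + (!is.na(idx_d))
  children <- vector("list", n)
  for (i in pos) {
    for (p in c(idx_s[i], idx_d[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  if (length(out) < n) stop_twinqtl("cycle in pedigree")
  out
}

#' Inbreeding coefficients
#'
#' Meuwissen-Luo ancestor-tracing inbreeding coefficients for a pedigree in
#' any order (a topological sort is applied internally; cycles are an
#' error).
#'
#' @param pedigree pedigree `data.frame` with `id`, `sire`, `dam`.
#' @return Numeric vector of inbreeding coefficients, one per input row.
#' @export
inbreeding_coefficients <- function(pedigree) {
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, , drop = FALSE]
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  f <- .ml_inbreeding(as.integer(s), as.integer(d))
  f[order(ord)]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles the inverse of the additive (numerator) relationship matrix by
#' Henderson's rules with the exact inbreeding-adjusted Mendelian-sampling
#' variances (Meuwissen-Luo diagonal), without ever forming A itself.
#'
#' @param pedigree pedigree `data.frame` with `id`, `sire`, `dam` in any
#'   acyclic order.
#' @return A list with `Ainv` (sparse symmetric `dsCMatrix`, rows/columns in
#'   input order, dimnames = animal ids), `inbreeding` (per-animal F), and
#'   `logdet_A` (log-determinant of A, used in the REML likelihood).
#' @export
build_a_inverse <- function(pedigree) {
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, , drop = FALSE]
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  f <- .ml_inbreeding(
    as.integer(ifelse(is.na(s), 0L, s)),
    as.integer(ifelse(is.na(d), 0L, d))
  )
  fs <- ifelse(is.na(s), -1, f[s]) # F of -1 encodes an unknown parent
  fd <- ifelse(is.na(d), -1, f[d])
  dvar <- 1 - 0.25 * (1 + fs) * (!is.na(s)) - 0.25 * (1 + fd) * (!is.na(d))
  b <- 1 / dvar
  i <- seq_len(n)

  ii <- c(i)
  jj <- c(i)
  xx <- c(b)
  ks <- !is.na(s)
  kd <- !is.na(d)
  # animal-parent and parent-parent contributions
  ii <- c(ii, i[ks], s[ks], s[ks], i[kd], d[kd], d[kd])
  jj <- c(jj, s[ks], i[ks], s[ks], d[kd], i[kd], d[kd])
  xx <- c(
    xx, -b[ks] / 2, -b[ks] / 2, b[ks] / 4,
    -b[kd] / 2, -b[kd] / 2, b[kd] / 4
  )
  both <- ks & kd
  ii <- c(ii, s[both], d[both])
  jj <- c(jj, d[both], s[both])
  xx <- c(xx, b[both] / 4, b[both] / 4)

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # back to input order
  perm <- order(ord)
  Ainv <- Ainv[perm, perm, drop = FALSE]
  Ainv <- methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
  dimnames(Ainv) <- list(pedigree$id, pedigree$id)
  list(
    Ainv = Ainv, inbreeding = f[perm],
    logdet_A = sum(log(dvar))
  )
}
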