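#' Build the design of the direct-maternal animal model
#'
#' Assembles the response and design matrices of the linear mixed model
#' `y = X b + W h + Z_d mb_d + Z_m mb_m + e`: fixed effects (parity, season,
#' sexed semen, age-of-dam covariate, intercept), random herd-year, and the
#' correlated direct (calf) and maternal (dam) additive genetic effects over
#' all pedigree animals.
#'
#' @param frame a `model_frame` from [encode_model_frame()].
#' @param pedigree the pedigree (all calves and dams must appear).
#' @return An object of class `model_design`: list with `y`, dense `X`,
#'   sparse `W`, `Zd`, `Zm`, the `pedigree`, `animal_ids`, and the
#'   `a_inverse` structure from [build_a_inverse()].
#' @export
build_model_design <- function(frame, pedigree) {
  stopifnot(inherits(frame, "data.frame"))
  y <- frame$code
  n <- length(y)
  frame <- droplevels(frame)
  X <- model.matrix(
    ~ parity + season + sexed_semen + age_months,
    data = frame
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_twinqtl(
      "singular fixed-effect block; confounded levels: ",
      paste(aliased, collapse = ", ")
    )
  }
  W <- Matrix::sparse.model.matrix(~ 0 + herd_year, data = frame)
  colnames(W) <- levels(frame$herd_year)
  ids <- pedigree$id
  calf_idx <- match(frame$calf, ids)
  dam_idx <- match(frame$dam, ids)
  if (anyNA(calf_idx) || anyNA(dam_idx)) {
    stop_twinqtl("calves or dams missing from the pedigree")
  }
  nA <- length(ids)
  Zd <- Matrix::sparseMatrix(i = seq_len(n), j = calf_idx, x = 1, dims = c(n, nA))
  Zm <- Matrix::sparseMatrix(i = seq_len(n), j = dam_idx, x = 1, dims = c(n, nA))
  ainv <- build_a_inverse(pedigree)
  Tm <- cbind(methods::as(X, "CsparseMatrix"), W, Zd, Zm)
  structure(
    list(
      y = y, X = X, W = W, Zd = Zd, Zm = Zm,
      pedigree = pedigree, animal_ids = ids, a_inverse = ainv,
      TtT = Matrix::crossprod(Tm), Tty = as.numeric(Matrix::crossprod(Tm, y))
    ),
    class = "model_design"
  )
}

# Assemble the mixed-model-equation coefficient matrix and right-hand side
# at a given parameter vector. Equation order: beta, h, a, m.
mme_build <- function(design, vc) {
  p <- ncol(design$X)
  qh <- ncol(design$W)
  nA <- length(design$animal_ids)
  G0 <- matrix(c(vc$direct, vc$covariance, vc$covariance, vc$maternal), 2, 2)
  G0i <- solve(G0)
  # explicit 2x2-block assembly keeps the sparsity pattern fixed even when
  # the covariance (hence an off-diagonal block) is exactly zero
  Ai <- methods::as(design$a_inverse$Ainv, "generalMatrix")
  Gblk <- rbind(
    cbind(G0i[1, 1] * Ai, G0i[1, 2] * Ai),
    cbind(G0i[2, 1] * Ai, G0i[2, 2] * Ai)
  )
  Dg <- Matrix::bdiag(
    Matrix::Diagonal(p, 0), Matrix::Diagonal(qh, 1 / vc$herd_year), Gblk
  )
  C <- design$TtT / vc$residual + Dg
  rhs <- design$Tty / vc$residual
  list(C = Matrix::forceSymmetric(C), rhs = rhs, p = p, qh = qh, nA = nA, G0 = G0)
}

# Split a solution vector into its blocks.
mme_split <- function(sol, p, qh, nA) {
  list(
    beta = sol[seq_len(p)],
    h = sol[p + seq_len(qh)],
    a = sol[p + qh + seq_len(nA)],
    m = sol[p + qh + nA + seq_len(nA)]
  )
}

# Fitted values T s for the record part.
mme_fitted <- function(design, blocks) {
  as.numeric(design$X %*% blocks$beta) +
    as.numeric(design$W %*% blocks$h) +
    as.numeric(design$Zd %*% blocks$a) +
    as.numeric(design$Zm %*% blocks$m)
}

#' AI-REML variance components of the direct-maternal animal model
#'
#' Estimates the five (co)variance components (herd-year, direct, maternal,
#' direct-maternal covariance, residual) by average-information REML on the
#' mixed-model equations. The average-information matrix is computed exactly
#' from working variates; the trace terms of the gradient use a Hutchinson
#' Monte-Carlo estimator with a fixed set of Rademacher probe vectors
#' (shared across iterations, so the iteration converges smoothly), each
#' probe costing one solve with the current sparse Cholesky factor. Steps
#' that leave the parameter space or fail to improve the (exact) restricted
#' log-likelihood are halved and, if necessary, replaced by an
#' expectation-maximization update. Variances are clamped at a small
#' positive floor; the covariance is kept inside the positive-definite
#' bound.
#'
#' @param design a [build_model_design()] object.
#' @param init optional starting [variance_components()]; a data-driven
#'   default is used otherwise.
#' @param tol convergence tolerance on the relative change of the restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter maximum AI iterations.
#' @param n_probes number of Monte-Carlo probe vectors for the gradient
#'   traces.
#' @param n_em_warmup number of stabilizing expectation-maximization
#'   iterations before switching to average-information steps (default 3;
#'   use 1 when `init` is already close to the optimum).
#' @param probe_seed seed of the probe draw; the default derives it from the
#'   response, which keeps results reproducible and invariant to record
#'   order while decorrelating the (small) Monte-Carlo perturbation across
#'   datasets.
#' @param verbose print the iteration trajectory.
#' @return A [variance_components()] object with standard errors from the
#'   inverse average-information matrix, plus attributes `loglik`,
#'   `iterations`, `converged` and `trajectory`.
#' @export
reml_variance_components <- function(design, init = NULL, tol = 1e-8,
                                     max_iter = 60, n_probes = 48,
                                     n_em_warmup = 3,
                                     probe_seed = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "model_design"))
  y <- design$y
  n <- length(y)
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop_twinqtl("response has no variance")
  if (is.null(init)) {
    init <- variance_components(
      herd_year = 0.05 * vy, direct = 0.05 * vy, maternal = 0.10 * vy,
      covariance = 0, residual = 0.80 * vy
    )
  }
  theta <- c(
    init$herd_year, init$direct, init$covariance, init$maternal, init$residual
  )
  floor_v <- 1e-10 * vy

  X <- design$X
  p <- ncol(X)
  qh <- ncol(design$W)
  nA <- length(design$animal_ids)
  n_eq <- p + qh + 2 * nA
  logdet_A <- design$a_inverse$logdet_A
  chA <- Matrix::Cholesky(design$a_inverse$Ainv, LDL = FALSE)
  Amult <- function(v) as.matrix(Matrix::solve(chA, v, system = "A"))

  if (is.null(probe_seed)) {
    probe_seed <- floor(abs(sum(y^2)) * 1e4) %% 2147483647
  }
  probes <- with_seed(probe_seed, {
    matrix(sample(c(-1, 1), n * n_probes, replace = TRUE), n, n_probes)
  })

  chol_cache <- NULL
  # one REML evaluation: factorize, solve, exact -2logL, Py
  evaluate <- function(theta) {
    vc <- theta_vc(theta)
    mm <- mme_build(design, vc)
    ch <- if (is.null(chol_cache)) {
      Matrix::Cholesky(mm$C, LDL = FALSE, super = TRUE)
    } else {
      tryCatch(
        Matrix::update(chol_cache, mm$C),
        error = function(e) Matrix::Cholesky(mm$C, LDL = FALSE, super = TRUE)
      )
    }
    chol_cache <<- ch
    sol <- as.numeric(Matrix::solve(ch, mm$rhs, system = "A"))
    blocks <- mme_split(sol, p, qh, nA)
    resid <- y - mme_fitted(design, blocks)
    Py <- resid / vc$residual
    yPy <- sum(y * Py)
    ldC <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
    ldG <- qh * log(vc$herd_year) + nA * log(det(mm$G0)) + 2 * logdet_A
    m2ll <- n * log(vc$residual) + ldG + ldC + yPy
    list(
      vc = vc, mm = mm, ch = ch, sol = sol, blocks = blocks,
      Py = Py, yPy = yPy, m2ll = m2ll
    )
  }

  # apply P to a matrix of record-space vectors via MME solves
  apply_P <- function(Z, ev) {
    rhs <- rbind(
      crossprod(X, Z),
      as.matrix(Matrix::crossprod(design$W, Z)),
      as.matrix(Matrix::crossprod(design$Zd, Z)),
      as.matrix(Matrix::crossprod(design$Zm, Z))
    ) / ev$vc$residual
    solm <- as.matrix(Matrix::solve(ev$ch, rhs, system = "A"))
    fit <- as.matrix(X %*% solm[seq_len(p), , drop = FALSE]) +
      as.matrix(design$W %*% solm[p + seq_len(qh), , drop = FALSE]) +
      as.matrix(design$Zd %*% solm[p + qh + seq_len(nA), , drop = FALSE]) +
      as.matrix(design$Zm %*% solm[p + qh + nA + seq_len(nA), , drop = FALSE])
    (Z - fit) / ev$vc$residual
  }

  # V_i applied to record-space vectors, i indexes theta
  apply_Vi <- function(i, Z) {
    switch(i,
      as.matrix(design$W %*% Matrix::crossprod(design$W, Z)), # herd-year
      as.matrix(design$Zd %*% Amult(Matrix::crossprod(design$Zd, Z))), # direct
      as.matrix(design$Zd %*% Amult(Matrix::crossprod(design$Zm, Z))) +
        as.matrix(design$Zm %*% Amult(Matrix::crossprod(design$Zd, Z))), # cov
      as.matrix(design$Zm %*% Amult(Matrix::crossprod(design$Zm, Z))), # maternal
      Z # residual
    )
  }

  theta_ok <- function(th) {
    th[1] >= floor_v && th[2] >= floor_v && th[4] >= floor_v &&
      th[5] >= floor_v && th[3]^2 <= 0.998 * th[2] * th[4]
  }
  project <- function(th) {
    th[c(1, 2, 4, 5)] <- pmax(th[c(1, 2, 4, 5)], floor_v)
    bound <- 0.99 * sqrt(th[2] * th[4])
    th[3] <- max(min(th[3], bound), -bound)
    th
  }
  theta_vc <- function(th) {
    variance_components(
      herd_year = th[1], direct = th[2], maternal = th[4],
      covariance = th[3], residual = th[5]
    )
  }
  # multiplicative trust region: no variance moves by more than 5x per step
  trust <- function(old, new) {
    for (i in c(1, 2, 4, 5)) {
      new[i] <- min(max(new[i], old[i] / 5), old[i] * 5)
    }
    new
  }

  theta <- project(theta)
  ev <- evaluate(theta)
  trajectory <- data.frame(
    iter = 0, m2ll = ev$m2ll, t(setNames(
      theta, c("herd_year", "direct", "covariance", "maternal", "residual")
    ))
  )
  converged <- FALSE
  AI <- NULL
  decrement <- Inf
  noise_floor <- 0
  for (iter in seq_len(max_iter)) {
    use_ai <- iter > n_em_warmup
    improved <- FALSE
    if (use_ai) {
      PZ <- apply_P(probes, ev)
      half <- seq_len(floor(n_probes / 2))
      tr_parts <- vapply(1:5, function(i) {
        v <- colSums(probes * apply_Vi(i, PZ))
        c(mean(v), mean(v[half]), mean(v[-half]))
      }, numeric(3))
      tr <- tr_parts[1, ]
      f <- vapply(1:5, function(i) apply_Vi(i, matrix(ev$Py)), numeric(n))
      Pf <- apply_P(f, ev)
      grad <- -0.5 * (tr - colSums(f * ev$Py))
      AI <- 0.5 * crossprod(f, Pf)
      AI <- (AI + t(AI)) / 2

      step <- tryCatch(solve(AI, grad), error = function(e) NULL)
      # Newton decrement along the feasible (projected, trust-region)
      # direction and its Monte-Carlo noise floor (from the two probe
      # half-sets): reported as diagnostics of how much likelihood the
      # next step could still gain versus probe noise
      decrement <- Inf
      noise_floor <- 0
      if (!is.null(step)) {
        d <- project(trust(theta, theta + step)) - theta
        gd <- sum(grad * d)
        dAId <- sum(d * (AI %*% d))
        decrement <- if (gd <= 0 || dAId <= 0) 0 else gd^2 / (2 * dAId)
        gnoise <- -0.5 * (tr_parts[2, ] - tr_parts[3, ]) / 2
        noise_floor <- if (dAId <= 0) 0 else sum(gnoise * d)^2 / (2 * dAId)
      }
      if (!is.null(step)) {
        lambda <- 1
        for (half in 1:8) {
          cand <- project(trust(theta, theta + lambda * step))
          ev_cand <- tryCatch(evaluate(cand), error = function(e) {
            if (verbose) message("step rejected: ", conditionMessage(e))
            NULL
          })
          if (!is.null(ev_cand) && is.finite(ev_cand$m2ll) &&
            ev_cand$m2ll <= ev$m2ll + 1e-10 * abs(ev$m2ll)) {
            improved <- TRUE
            break
          }
          lambda <- lambda / 2
        }
      }
    }
    if (!improved) {
      cand <- project(em_step(theta, ev, design, n_probes, p, qh, nA))
      ev_cand <- tryCatch(evaluate(cand), error = function(e) {
        if (verbose) message("EM step rejected: ", conditionMessage(e))
        NULL
      })
      if (is.null(ev_cand) || !is.finite(ev_cand$m2ll)) {
        stop_twinqtl(
          "REML failed to converge after ", iter, " iterations; last -2logL ",
          signif(ev$m2ll, 10)
        )
      }
    }
    delta <- abs(ev$m2ll - ev_cand$m2ll) / (abs(ev$m2ll) + 1e-30)
    theta <- cand
    ev <- ev_cand
    trajectory <- rbind(trajectory, data.frame(
      iter = iter, m2ll = ev$m2ll, t(setNames(
        theta, c("herd_year", "direct", "covariance", "maternal", "residual")
      ))
    ))
    if (verbose) {
      message(sprintf(
        "it %2d  -2logL %.6f  h %.3e a %.3e am %.3e m %.3e e %.3e",
        iter, ev$m2ll, theta[1], theta[2], theta[3], theta[4], theta[5]
      ))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_twinqtl(
      "REML did not converge in ", max_iter, " iterations (last rel. change ",
      signif(delta, 3), ", Newton decrement ", signif(decrement, 3),
      "); trajectory attached"
    )
  }
  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, 5))
  out <- variance_components(
    herd_year = theta[1], direct = theta[2], maternal = theta[4],
    covariance = theta[3], residual = theta[5],
    se = setNames(
      se[c(1, 2, 4, 3, 5)],
      c("herd_year", "direct", "maternal", "covariance", "residual")
    )
  )
  attr(out, "loglik") <- -ev$m2ll / 2
  attr(out, "iterations") <- nrow(trajectory) - 1
  attr(out, "converged") <- converged
  attr(out, "trajectory") <- trajectory
  attr(out, "newton_decrement") <- decrement
  attr(out, "decrement_noise_floor") <- noise_floor
  out
}

# One EM-flavoured fallback update (used when the AI step is rejected).
em_step <- function(theta, ev, design, np, p, qh, nA) {
  n <- length(design$y)
  blocks <- ev$blocks
  # MC estimates of tr(C^{hh}) and tr(Ainv C^{uu}) blocks
  zh <- with_seed(29, matrix(sample(c(-1, 1), (qh + 2 * nA) * np, replace = TRUE), ncol = np))
  rhs <- rbind(matrix(0, p, np), zh)
  w <- as.matrix(Matrix::solve(ev$ch, rhs, system = "A"))
  zh_h <- zh[seq_len(qh), , drop = FALSE]
  zh_a <- zh[qh + seq_len(nA), , drop = FALSE]
  zh_m <- zh[qh + nA + seq_len(nA), , drop = FALSE]
  w_h <- w[p + seq_len(qh), , drop = FALSE]
  w_a <- w[p + qh + seq_len(nA), , drop = FALSE]
  w_m <- w[p + qh + nA + seq_len(nA), , drop = FALSE]
  Ainv <- design$a_inverse$Ainv
  tr_hh <- mean(colSums(zh_h * w_h))
  tr_aa <- mean(colSums(as.matrix(Ainv %*% w_a) * zh_a))
  tr_mm <- mean(colSums(as.matrix(Ainv %*% w_m) * zh_m))
  tr_am <- mean(colSums(as.matrix(Ainv %*% w_a) * zh_m))
  Uq <- cbind(blocks$a, blocks$m)
  quad <- crossprod(Uq, as.matrix(Ainv %*% Uq))
  Tmat <- matrix(c(tr_aa, tr_am, tr_am, tr_mm), 2, 2)
  G0_new <- (quad + Tmat) / nA
  G0_new <- (G0_new + t(G0_new)) / 2
  s2h_new <- (sum(blocks$h^2) + tr_hh) / qh
  s2e_new <- theta[5] * ev$yPy / (n - p)
  c(s2h_new, G0_new[1, 1], G0_new[1, 2], G0_new[2, 2], s2e_new)
}
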