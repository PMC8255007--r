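test_that("A-inverse handles founders and the classic trio", {
  one <- build_a_inverse(data.frame(id = 1, sire = NA, dam = NA))
  expect_equal(as.matrix(one$Ainv), matrix(1, 1, 1, dimnames = list(1, 1)))

  trio <- build_a_inverse(
    data.frame(id = 1:3, sire = c(NA, NA, 1), dam = c(NA, NA, 2))
  )
  M <- as.matrix(trio$Ainv)
  expect_equal(M[1, 1], 1.5)
  expect_equal(M[3, 3], 2)
  expect_equal(M[1, 2], 0.5)
  expect_equal(M[1, 3], -1)
})

test_that("A-inverse inverts the tabular relationship matrix", {
  cfg <- sim_config(
    seed = 17, n_founders = 18, founder_female_frac = 0.7,
    n_generations = 3, offspring_per_generation = 12
  )
  ped <- simulate_pedigree(cfg)
  expect_gte(nrow(ped), 50)
  A <- tabular_a(ped)
  ai <- build_a_inverse(ped)
  expect_lt(max(abs(A %*% as.matrix(ai$Ainv) - diag(nrow(ped)))), 1e-8)
  expect_equal(ai$logdet_A, as.numeric(determinant(A)$modulus))
  expect_equal(ai$inbreeding, diag(A) - 1)
})

test_that("inbreeding of a full-sib mating is 1/4", {
  ped <- data.frame(
    id = 1:5, sire = c(NA, NA, 1, 1, 3), dam = c(NA, NA, 2, 2, 4)
  )
  expect_equal(inbreeding_coefficients(ped), c(0, 0, 0, 0, 0.25))
})

test_that("cycles in the pedigree are refused", {
  ped <- data.frame(id = 1:2, sire = c(2, 1), dam = c(NA, NA))
  expect_error(build_a_inverse(ped), "cycle")
})

test_that("heritability limits behave", {
  expect_equal(
    heritabilities(variance_components(0, 0, 0, 0, 1)),
    c(direct = 0, maternal = 0)
  )
  s <- 0.1
  expect_equal(
    heritabilities(variance_components(0, s, s, 0, s)),
    c(direct = 1 / 3, maternal = 1 / 3)
  )
  expect_error(
    variance_components(0, 1e-6, 1e-6, 1, 1),
    "covariance exceeds"
  )
})

test_that("restricted likelihood matches the dense brute-force value", {
  cfg <- sim_config(
    seed = 19, n_founders = 40, founder_female_frac = 0.75,
    n_generations = 3, offspring_per_generation = 28, n_herds = 3,
    qtl = NULL
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des <- build_model_design(encode_model_frame(rec, ped), ped)
  # at an arbitrary valid parameter point
  vc <- variance_components(2e-4, 1e-4, 1.5e-3, -1e-4, 0.03)
  ev <- twinqtl:::mme_build(des, vc)
  fit <- blup_solve(des, vc, pev = FALSE)
  Py <- (des$y - with(fit, as.numeric(
    des$X %*% fixed + des$W %*% herd_year +
      des$Zd %*% ebv$ebv[seq_along(des$animal_ids)] +
      des$Zm %*% ebv$ebv[length(des$animal_ids) + seq_along(des$animal_ids)]
  ))) / vc$residual
  ch <- Matrix::Cholesky(ev$C, LDL = FALSE)
  m2 <- length(des$y) * log(vc$residual) +
    ev$qh * log(vc$herd_year) + ev$nA * log(det(ev$G0)) +
    2 * des$a_inverse$logdet_A +
    as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus) +
    sum(des$y * Py)
  expect_equal(m2, dense_m2ll(des, vc), tolerance = 1e-6)

  # and at the REML optimum reached by the package (the toy's boundary
  # optimum is shallow, so a modest tolerance is used for the fit itself;
  # the likelihood-value comparison stays at 1e-6)
  res <- reml_variance_components(des, tol = 1e-5, max_iter = 80)
  expect_equal(-2 * attr(res, "loglik"), dense_m2ll(des, res),
    tolerance = 1e-6
  )
})

test_that("a zero direct variance stays statistically at the boundary", {
  cfg <- sim_config(
    seed = 23, n_founders = 1100, founder_female_frac = 10 / 11,
    n_generations = 4, offspring_per_generation = 1000, n_herds = 20,
    years = 2006:2009, qtl = NULL
  )
  cfg$variance_components <- variance_components(
    herd_year = 0.992e-4, direct = 0, maternal = 0.130e-2,
    covariance = 0, residual = 0.036
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des <- build_model_design(encode_model_frame(rec, ped), ped)
  res <- reml_variance_components(des, tol = 1e-6, max_iter = 80)
  # the estimate respects the non-negativity floor and is small in
  # absolute terms
  expect_gte(res$direct, 0)
  expect_lt(res$direct / res$residual, 0.05)
  # and it is statistically indistinguishable from the boundary: the
  # estimate lies within its own AI standard error band of zero, and
  # forcing the direct variance (with the covariance it bounds) to the
  # floor costs almost no restricted likelihood
  se_a <- res$se[["direct"]]
  if (is.finite(se_a)) expect_lt(res$direct, 4 * se_a)
  # profile the restricted likelihood with the direct variance (and the
  # covariance it bounds) held at the floor: the constrained optimum must
  # cost only a few log-likelihood units
  m2_at <- function(vc) {
    fit0 <- blup_solve(des, vc, pev = FALSE)
    mm <- twinqtl:::mme_build(des, vc)
    ch <- Matrix::Cholesky(mm$C, LDL = FALSE)
    Py <- (des$y - with(fit0, as.numeric(
      des$X %*% fixed + des$W %*% herd_year +
        des$Zd %*% ebv$ebv[seq_along(des$animal_ids)] +
        des$Zm %*% ebv$ebv[length(des$animal_ids) + seq_along(des$animal_ids)]
    ))) / vc$residual
    length(des$y) * log(vc$residual) +
      mm$qh * log(vc$herd_year) + mm$nA * log(det(mm$G0)) +
      2 * des$a_inverse$logdet_A +
      as.numeric(
        Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus
      ) +
      sum(des$y * Py)
  }
  prof <- optim(
    log(c(res$herd_year, res$maternal + res$covariance, res$residual)),
    function(lp) {
      m2_at(variance_components(
        exp(lp[1]), 1e-10, max(exp(lp[2]), 1e-8), 0, exp(lp[3])
      ))
    },
    method = "Nelder-Mead", control = list(maxit = 80)
  )
  expect_lt(prof$value - (-2 * attr(res, "loglik")), 6)
})

test_that("REML estimates are invariant to record order", {
  # well-conditioned components so the optimum is sharp: record order can
  # then only perturb floating-point summation, not the solution
  cfg <- small_config(
    seed = 29, n_founders = 120, offspring_per_generation = 80,
    variance_components = variance_components(0.02, 0.05, 0.08, 0.01, 0.3)
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des1 <- build_model_design(encode_model_frame(rec, ped), ped)
  set.seed(1)
  perm <- sample(nrow(rec))
  des2 <- build_model_design(encode_model_frame(rec[perm, ], ped), ped)
  # at fixed components every quantity is exactly order-invariant
  vc <- variance_components(0.02, 0.05, 0.08, 0.01, 0.3)
  f1 <- blup_solve(des1, vc, pev = FALSE)
  f2 <- blup_solve(des2, vc, pev = FALSE)
  expect_lt(max(abs(f1$ebv$ebv - f2$ebv$ebv)), 1e-10)
  expect_lt(max(abs(f1$fixed - f2$fixed)), 1e-10)
  # the full REML endpoint can only drift by floating-point path noise
  # within the likelihood's flat region: likelihoods and the
  # well-determined components must agree
  r1 <- reml_variance_components(des1, tol = 1e-6, max_iter = 80)
  r2 <- reml_variance_components(des2, tol = 1e-6, max_iter = 80)
  expect_equal(attr(r1, "loglik"), attr(r2, "loglik"), tolerance = 1e-2)
  expect_equal(r1$residual, r2$residual, tolerance = 0.02)
  expect_equal(r1$maternal, r2$maternal, tolerance = 0.2)
})

test_that("BLUP solutions equal dense GLS and satisfy the MME", {
  cfg <- sim_config(
    seed = 31, n_founders = 90, founder_female_frac = 0.75,
    n_generations = 4, offspring_per_generation = 60, n_herds = 3,
    qtl = NULL
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des <- build_model_design(encode_model_frame(rec, ped), ped)
  vc <- reference_variance_components()
  fit <- blup_solve(des, vc)
  oracle <- dense_gls(des, vc)
  nA <- length(des$animal_ids)
  expect_lt(max(abs(fit$fixed - oracle$fixed)), 1e-8)
  expect_lt(max(abs(fit$ebv$ebv[seq_len(nA)] - oracle$mbd)), 1e-8)
  expect_lt(max(abs(fit$ebv$ebv[nA + seq_len(nA)] - oracle$mbm)), 1e-8)
  expect_lt(
    max(abs(as.numeric(
      fit$mme$C %*% fit$mme$solution - fit$mme$rhs
    ))), 1e-8
  )
})

test_that("an unconnected animal without records gets EBV zero", {
  cfg <- small_config(seed = 37)
  ped <- simulate_pedigree(cfg)
  extra <- ped[1, ]
  extra$id <- max(ped$id) + 1L
  extra$sire <- extra$dam <- NA
  ped2 <- rbind(ped, extra)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des <- build_model_design(encode_model_frame(rec, ped2), ped2)
  fit <- blup_solve(des, reference_variance_components(), pev = TRUE)
  loner <- fit$ebv[fit$ebv$animal == extra$id, ]
  expect_equal(loner$ebv, c(0, 0))
  # and its PEV equals the full genetic variance (reliability zero)
  rel <- reliability(loner, reference_variance_components())
  expect_equal(rel$reliability, c(0, 0), tolerance = 1e-8)
})

test_that("well-specified maternal variance ranks dams better", {
  cfg <- sim_config(
    seed = 41, n_founders = 500, founder_female_frac = 0.8,
    n_generations = 4, offspring_per_generation = 350, n_herds = 5,
    qtl = NULL
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  truth <- attr(rec, "truth")
  des <- build_model_design(encode_model_frame(rec, ped), ped)
  vc_good <- reference_variance_components()
  vc_bad <- variance_components(
    vc_good$herd_year, vc_good$direct, vc_good$maternal / 10,
    vc_good$covariance / 10, vc_good$residual
  )
  nA <- length(des$animal_ids)
  mbm_good <- blup_solve(des, vc_good, pev = FALSE)$ebv$ebv[nA + seq_len(nA)]
  mbm_bad <- blup_solve(des, vc_bad, pev = FALSE)$ebv$ebv[nA + seq_len(nA)]
  dams <- unique(rec$dam)
  idx <- match(dams, des$animal_ids)
  # BLUP at the true components is calibrated: E[u | u_hat] = u_hat, so the
  # regression of true on predicted values has slope near 1; an evaluation
  # run with the maternal variance understated ten-fold over-shrinks and
  # pushes the slope far above 1
  slope_good <- coef(lm(truth$bv[idx, "maternal"] ~ mbm_good[idx]))[2]
  slope_bad <- coef(lm(truth$bv[idx, "maternal"] ~ mbm_bad[idx]))[2]
  expect_gt(slope_good, 0.6)
  expect_lt(slope_good, 1.4)
  expect_gt(slope_bad, slope_good + 0.5)
  expect_gt(cor(mbm_good[idx], truth$bv[idx, "maternal"]), 0.2)
})

test_that("exact PEV agrees with a resampling experiment", {
  cfg <- sim_config(
    seed = 43, n_founders = 50, founder_female_frac = 0.7,
    n_generations = 3, offspring_per_generation = 30, n_herds = 3,
    qtl = NULL
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  des <- build_model_design(encode_model_frame(rec, ped), ped)
  vc <- variance_components(0.02, 0.05, 0.08, 0.01, 0.3)
  fit <- blup_solve(des, vc, pev = TRUE)
  nA <- length(des$animal_ids)

  G0 <- matrix(c(vc$direct, vc$covariance, vc$covariance, vc$maternal), 2, 2)
  A <- solve(as.matrix(des$a_inverse$Ainv))
  L <- t(chol(kronecker(G0, A)))
  mm <- twinqtl:::mme_build(des, vc)
  ch <- Matrix::Cholesky(mm$C, LDL = FALSE)
  n <- length(des$y)
  qh <- ncol(des$W)
  set.seed(99)
  R <- 400
  err <- matrix(0, R, 2 * nA)
  for (r in seq_len(R)) {
    u <- as.numeric(L %*% rnorm(2 * nA))
    h <- rnorm(qh, 0, sqrt(vc$herd_year))
    y <- as.numeric(
      des$W %*% h + des$Zd %*% u[seq_len(nA)] +
        des$Zm %*% u[nA + seq_len(nA)]
    ) + rnorm(n, 0, sqrt(vc$residual))
    Tm <- cbind(
      methods::as(des$X, "CsparseMatrix"), des$W, des$Zd, des$Zm
    )
    rhs <- as.numeric(Matrix::crossprod(Tm, y)) / vc$residual
    sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    err[r, ] <- sol[mm$p + qh + seq_len(2 * nA)] - u
  }
  emp <- apply(err, 2, var)
  exact <- fit$ebv$pev
  expect_equal(mean(emp), mean(exact), tolerance = 0.1)
  expect_gt(cor(emp, exact), 0.9)
})

test_that("standardization puts the base group at exactly 100 / 12", {
  set.seed(5)
  ped <- data.frame(
    id = 1:200, sire = NA, dam = NA,
    sex = rep(c("M", "F"), 100),
    birth_year = rep(c(2002, 2010), each = 100),
    breed_HOL = 1, breed_SIM = 0
  )
  ebv <- data.frame(
    animal = rep(1:200, 2), trait = rep(c("mbd", "mbm"), each = 200),
    ebv = rnorm(400)
  )
  std <- standardize_ebv(ebv, ped, eval_year = 2011)
  base <- ped$id[ped$sex == "M" & ped$birth_year == 2002]
  for (tr in c("mbd", "mbm")) {
    v <- std$ebv_std[std$trait == tr & std$animal %in% base]
    expect_equal(mean(v), 100, tolerance = 1e-10)
    expect_equal(sd(v), 12, tolerance = 1e-10)
  }
  # affine invariance: doubling raw EBVs changes nothing
  ebv2 <- ebv
  ebv2$ebv <- 2 * ebv2$ebv + 5
  std2 <- standardize_ebv(ebv2, ped, eval_year = 2011)
  expect_equal(std2$ebv_std, std$ebv_std, tolerance = 1e-10)
  # degenerate base group
  ebv3 <- ebv
  ebv3$ebv <- 1
  expect_error(standardize_ebv(ebv3, ped, eval_year = 2011), "zero SD")
})

test_that("genetic trend is flat for equal EBVs and rises under selection", {
  ped <- data.frame(
    id = 1:300, sire = NA, dam = NA, sex = "F",
    birth_year = rep(2001:2010, each = 30)
  )
  flat <- data.frame(animal = 1:300, trait = "mbm", ebv_std = 100)
  tr <- genetic_trend(flat, ped)
  expect_true(all(tr$mean == 100))
  expect_equal(unname(coef(lm(mean ~ year, tr))["year"]), 0)

  set.seed(11)
  up <- data.frame(
    animal = 1:300, trait = "mbm",
    ebv_std = 100 + 0.8 * (ped$birth_year - 2001) + rnorm(300, 0, 2)
  )
  tru <- genetic_trend(up, ped)
  fit <- summary(lm(mean ~ year, tru))
  expect_gt(coef(fit)["year", "t value"], 2)
})
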