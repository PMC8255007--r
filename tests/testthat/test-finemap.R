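# Hand-made panel builder: dosage matrix with explicit families.
manual_panel <- function(geno, families = NULL, breeds = NULL, pos = NULL) {
  n <- nrow(geno)
  ids <- rownames(geno) %||% as.character(seq_len(n))
  rownames(geno) <- ids
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("v", seq_len(ncol(geno)))
  }
  structure(
    list(
      variants = data.frame(
        chrom = 1, pos = pos %||% seq(1e5, by = 1e4, length.out = ncol(geno)),
        ref = "A", alt = "C", flip_rate = NA, linked = FALSE
      ),
      geno = geno,
      samples = data.frame(
        id = ids, breed = breeds %||% rep("HOL", n)
      ),
      families = families %||% data.frame(
        child = character(0), sire = character(0), dam = character(0)
      )
    ),
    class = "seq_panel"
  )
}

test_that("duo and trio error definitions", {
  geno <- rbind(
    p1 = c(0, 0, 1), p2 = c(2, 1, 1), ch = c(2, 1, 1)
  )
  fam_duo <- data.frame(child = "ch", sire = "p1", dam = NA)
  out <- mendelian_error_rate(manual_panel(geno, fam_duo))
  # parent 0/0 vs child 1/1 at variant 1 is an opposing-homozygote error
  expect_equal(out$per_variant$errors, c(1, 0, 0))
  expect_equal(out$n_duos, 1)

  fam_trio <- data.frame(child = "ch", sire = "p1", dam = "p2")
  # variant 1: parents 0/0 x 1/1 must give 0/1 -> child 0/0 is an error;
  # variants 2-3: parents carry a het, child 0/0 is consistent
  geno2 <- geno
  geno2["ch", ] <- c(1, 0, 0)
  out2 <- mendelian_error_rate(manual_panel(geno2, fam_trio))
  expect_equal(out2$per_variant$errors, c(0, 0, 0))
  geno3 <- geno
  geno3["ch", ] <- c(0, 0, 0)
  out3 <- mendelian_error_rate(manual_panel(geno3, fam_trio))
  expect_equal(out3$per_variant$errors, c(1, 0, 0))
  expect_equal(out3$n_trios, 1)
})

test_that("trio consistency matches exhaustive enumeration", {
  enumerate_ok <- function(gc, gp, gm) {
    pa <- if (gp == 0) 0 else if (gp == 2) 1 else c(0, 1)
    ma <- if (gm == 0) 0 else if (gm == 2) 1 else c(0, 1)
    gc %in% outer(pa, ma, "+")
  }
  grid <- expand.grid(gc = 0:2, gp = 0:2, gm = 0:2)
  got <- with(grid, twinqtl:::trio_consistent(gc, gp, gm))
  want <- mapply(enumerate_ok, grid$gc, grid$gp, grid$gm)
  expect_equal(got, want)
})

test_that("random families match a brute-force error count", {
  set.seed(13)
  n <- 30
  m <- 40
  geno <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m)
  rownames(geno) <- paste0("a", 1:n)
  fam <- data.frame(
    child = paste0("a", 11:20), sire = paste0("a", 1:10),
    dam = c(paste0("a", 21:25), rep(NA, 5))
  )
  panel <- manual_panel(geno, fam)
  out <- mendelian_error_rate(panel)

  bf_err <- numeric(m)
  bf_tst <- numeric(m)
  for (k in seq_len(nrow(fam))) {
    gc <- geno[fam$child[k], ]
    gp <- geno[fam$sire[k], ]
    if (!is.na(fam$dam[k])) {
      gm <- geno[fam$dam[k], ]
      ok <- twinqtl:::trio_consistent(gc, gp, gm)
      bf_err <- bf_err + !ok
    } else {
      bf_err <- bf_err + (abs(gc - gp) == 2)
    }
    bf_tst <- bf_tst + 1
  }
  expect_equal(out$per_variant$errors, bf_err)
  expect_equal(out$per_variant$tested, bf_tst)
})

test_that("QC thresholds are strict on missingness, inclusive on MAF", {
  set.seed(14)
  n <- 100
  base <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  # variant 1: 11% missing (drop), variant 2: 10% missing (keep)
  base[1:11, 1] <- NA
  base[1:10, 2] <- NA
  panel <- manual_panel(base)
  out <- vcf_qc(panel)
  expect_equal(
    out$report$n[out$report$rule == "variant_missingness"], 1
  )
  expect_true("v2" %in% colnames(out$panel$geno))
  expect_false("v1" %in% colnames(out$panel$geno))
})

test_that("a panel without family links passes the Mendelian rule untouched", {
  set.seed(15)
  geno <- matrix(rbinom(600, 2, 0.5), 30, 20)
  out <- vcf_qc(manual_panel(geno))
  expect_equal(out$report$n[out$report$rule == "mendelian_samples"], 0)
  expect_equal(out$report$n[out$report$rule == "mendelian_variants"], 0)
})

test_that("QC removals match a brute-force filter with planted violations", {
  set.seed(16)
  n <- 60
  m <- 30
  geno <- matrix(rbinom(n * m, 2, runif(m, 0.3, 0.7)), n, m)
  rownames(geno) <- paste0("s", 1:n)
  geno[1:20, 1] <- NA # variant missingness 33%
  geno[, 2] <- c(rep(1, 1), rep(0, n - 1)) # MAF below 1%
  geno[1, 5:25] <- NA # sample s1 missingness 21/29 of surviving variants
  fam <- data.frame(child = "s2", sire = "s3", dam = NA)
  geno["s2", 6:30] <- 0
  geno["s3", 6:30] <- 2 # sample s2/s3 Mendelian rate near 1
  panel <- manual_panel(geno, fam)
  out <- vcf_qc(panel)

  # brute force, same rule order
  g <- geno
  keep_v <- colMeans(is.na(g)) <= 0.1
  g <- g[, keep_v, drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  keep_v2 <- pmin(p, 1 - p) >= 0.01
  g <- g[, keep_v2, drop = FALSE]
  keep_s <- rowMeans(is.na(g)) <= 0.1
  g <- g[keep_s, , drop = FALSE]
  expect_equal(
    out$report$n[out$report$rule == "variant_missingness"],
    sum(!keep_v)
  )
  expect_equal(out$report$n[out$report$rule == "variant_maf"], sum(!keep_v2))
  expect_equal(
    out$report$n[out$report$rule == "sample_missingness"], sum(!keep_s)
  )
  expect_gt(out$report$n[out$report$rule == "mendelian_samples"], 0)
  # conservation
  rep <- out$report
  expect_equal(
    sum(rep$n[rep$rule %in% c(
      "variant_missingness", "variant_maf", "mendelian_variants"
    )]) + ncol(out$panel$geno),
    m
  )
})

test_that("LD against the diplotype: identity, allele swap, skipping", {
  set.seed(17)
  n <- 100
  dip <- setNames(rbinom(n, 2, 0.3), paste0("s", 1:n))
  geno <- cbind(
    same = dip, swapped = 2 - dip, const = rep(1, n),
    noise = rbinom(n, 2, 0.5)
  )
  rownames(geno) <- names(dip)
  panel <- manual_panel(geno)
  ld <- haplotype_variant_ld(dip, panel, r2_floor = 0)
  expect_equal(ld$r2[ld$variant == "same"], 1, tolerance = 1e-12)
  expect_equal(ld$r2[ld$variant == "swapped"], 1, tolerance = 1e-12)
  expect_true("const" %in% attr(ld, "skipped"))
  expect_false("const" %in% ld$variant)
  # sorted descending, floor honoured
  expect_true(all(diff(ld$r2) <= 0))
  ld7 <- haplotype_variant_ld(dip, panel, r2_floor = 0.7)
  expect_true(all(ld7$r2 >= 0.7))
})

test_that("flip-ladder ranking is reproduced in every replicate", {
  for (s in 1:3) {
    cfg <- sim_config(
      seed = 70 + s, n_founders = 300, founder_female_frac = 0.75,
      n_generations = 2, offspring_per_generation = 200, n_herds = 4,
      n_chromosomes = 1, snps_per_chromosome = 40, chromosome_length = 2e6,
      qtl = list(
        chrom = 1, start = 9e5, end = 1.1e6, effect = -1, target_freq = 0.3
      ),
      seq_panel = list(
        window = c(6e5, 1.4e6), n_linked = 3,
        flip_rates = c(0.02, 0.1, 0.2), n_independent = 3,
        missing_rate = 0, n_samples = 350
      )
    )
    ped <- simulate_pedigree(cfg)
    g <- simulate_genotypes(ped, cfg)
    panel <- simulate_seq_panel(g, cfg)
    dip <- qtl_diplotype(g)
    ld <- haplotype_variant_ld(dip, panel, r2_floor = 0)
    linked <- which(panel$variants$linked)
    r2 <- ld$r2[match(colnames(panel$geno)[linked], ld$variant)]
    fr <- panel$variants$flip_rate[linked]
    expect_equal(cor(-fr, r2, method = "spearman"), 1)
    expect_equal(
      ld$variant[1],
      colnames(panel$geno)[attr(panel, "causal_proxy")]
    )
  }
})

test_that("breed frequencies respect the inclusive 50-record bound", {
  set.seed(18)
  n <- 149
  geno <- matrix(rbinom(n, 2, 0.4), n, 1)
  breeds <- c(rep("HOL", 50), rep("SIM", 49), rep("OBV", 50))
  panel <- manual_panel(geno, breeds = breeds)
  bf <- breed_frequencies(panel, 1)
  expect_setequal(bf$breed, c("HOL", "OBV"))
  # hand tally
  expect_equal(
    bf$freq[bf$breed == "HOL"],
    mean(geno[breeds == "HOL", 1]) / 2
  )
  # fixed-for-reference breed
  geno2 <- geno
  geno2[breeds == "HOL", 1] <- 0
  bf2 <- breed_frequencies(manual_panel(geno2, breeds = breeds), 1)
  expect_equal(bf2$freq[bf2$breed == "HOL"], 0)
})
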