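test_that("minimal trio pedigree and determinism", {
  cfg <- sim_config(
    seed = 1, n_founders = 2, founder_female_frac = 0.5,
    n_generations = 1, offspring_per_generation = 1, n_herds = 1
  )
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire[1:2])))
  expect_equal(ped$sire[3], ped$id[ped$sex == "M"][1])
  expect_equal(ped$dam[3], ped$id[ped$sex == "F"][1])

  ped2 <- simulate_pedigree(cfg)
  expect_identical(ped, ped2)
})

test_that("multi-generation pedigree passes the topological audit", {
  cfg <- sim_config(
    seed = 5, n_founders = 40, founder_female_frac = 0.75,
    n_generations = 4, offspring_per_generation = 25
  )
  ped <- simulate_pedigree(cfg)
  expect_true(validate_pedigree(ped))
  pos <- seq_len(nrow(ped))
  is_founder <- is.na(ped$sire)
  expect_true(all(match(ped$sire[!is_founder], ped$id) < pos[!is_founder]))
  expect_true(all(match(ped$dam[!is_founder], ped$id) < pos[!is_founder]))
  # every non-founder has both parents, of the right sex
  expect_true(all(ped$sex[match(ped$sire[!is_founder], ped$id)] == "M"))
  expect_true(all(ped$sex[match(ped$dam[!is_founder], ped$id)] == "F"))
})

test_that("impossible mating structures fail loudly", {
  cfg <- sim_config(
    seed = 1, n_founders = 30, founder_female_frac = 0.2,
    n_generations = 1, offspring_per_generation = 25
  )
  expect_error(simulate_pedigree(cfg), "impossible mating structure")
})

test_that("zero recombination copies a parental haplotype exactly", {
  cfg <- small_config(seed = 2, recomb_rate = 0)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  nonf <- which(!is.na(ped$sire))
  for (i in nonf[1:10]) {
    sr <- match(ped$sire[i], ped$id)
    dr <- match(ped$dam[i], ped$id)
    expect_true(
      all(g$H2[i, ] == g$H1[sr, ]) || all(g$H2[i, ] == g$H2[sr, ])
    )
    expect_true(
      all(g$H1[i, ] == g$H1[dr, ]) || all(g$H1[i, ] == g$H2[dr, ])
    )
  }
})

test_that("a single founder haplotype makes everyone homozygous", {
  cfg <- small_config(seed = 3, founder_pool_size = 1)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_true(all(dosages(g) %in% c(0, 2)))
})

test_that("gene dropping is Mendelian-consistent at every marker", {
  cfg <- small_config(seed = 4)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  d <- dosages(g)
  nonf <- which(!is.na(ped$sire))
  sr <- match(ped$sire[nonf], ped$id)
  dr <- match(ped$dam[nonf], ped$id)
  # child dosage must lie in the range reachable from parental transmissions
  pa <- d[sr, , drop = FALSE]
  ma <- d[dr, , drop = FALSE]
  lo <- (pa == 2) + (ma == 2)
  hi <- 2 - (pa == 0) - (ma == 0)
  ch <- d[nonf, , drop = FALSE]
  expect_true(all(ch >= lo & ch <= hi))
})

test_that("the planted haplotype reaches its target frequency", {
  cfg <- sim_config(
    seed = 8, n_founders = 900, founder_female_frac = 0.75,
    n_generations = 2, offspring_per_generation = 650, n_herds = 5,
    n_chromosomes = 1, snps_per_chromosome = 60, chromosome_length = 2e6,
    qtl = list(chrom = 1, start = 9e5, end = 1.05e6, effect = -1,
      target_freq = 0.275)
  )
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  expect_gt(nrow(ped), 2000 - 1)
  freq <- mean(qtl_diplotype(g)) / 2
  expect_lt(abs(freq - 0.275), 0.05)
})

test_that("degenerate phenotype configuration yields identical records", {
  cfg <- small_config(seed = 6)
  cfg$variance_components <- variance_components(0, 0, 0, 0, 0)
  cfg$fixed_effects$parity <- rep(0.3, 5)
  cfg$fixed_effects$sexed <- c(no = 0, yes = 0)
  cfg$fixed_effects$season <- c(spring = 0, summer = 0, fall = 0, winter = 0)
  cfg$fixed_effects$age_slope <- 0
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  expect_equal(length(unique(rec$code)), 1)
})

test_that("herd-year effect variance matches its configured value", {
  cfg <- sim_config(
    seed = 9, n_founders = 21000, founder_female_frac = 20000 / 21000,
    n_generations = 5, offspring_per_generation = 20000, n_herds = 400,
    years = 2006:2010, qtl = NULL, snps_per_chromosome = 1
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  expect_gte(nrow(rec), 1e5)
  truth <- attr(rec, "truth")
  s2h <- var(truth$herd_year)
  expect_lt(abs(s2h - cfg$variance_components$herd_year) /
    cfg$variance_components$herd_year, 0.10)
  # and the realized herd-year means reflect it over and above noise
  hy <- paste(rec$herd, rec$year)
  res <- rec$code - ave(rec$code, hy)
  expect_lt(var(res), var(rec$code))
})

test_that("binary mode calibrates to the target prevalence", {
  cfg <- sim_config(
    seed = 10, n_founders = 42000, founder_female_frac = 40000 / 42000,
    n_generations = 5, offspring_per_generation = 40000, n_herds = 100,
    years = 2006:2010, qtl = NULL, snps_per_chromosome = 1,
    phenotype_mode = "binary"
  )
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, NULL, cfg)
  expect_gte(nrow(rec), 2e5)
  expect_lt(abs(multiple_birth_rate(rec) - 0.0356), 0.003)
})

test_that("simulation outputs are deterministic given the configuration", {
  cfg <- small_config(
    seed = 11,
    qtl = list(chrom = 1, start = 4e5, end = 6e5, effect = -0.02,
      target_freq = 0.3),
    seq_panel = list(window = c(3e5, 7e5), n_linked = 3,
      flip_rates = c(0.02, 0.1, 0.2), n_independent = 2,
      missing_rate = 0.05, n_samples = 50)
  )
  run <- function() {
    ped <- simulate_pedigree(cfg)
    g <- simulate_genotypes(ped, cfg)
    rec <- simulate_phenotypes(ped, g, cfg)
    panel <- simulate_seq_panel(g, cfg)
    list(ped, g$H1, g$H2, rec$code, panel$geno)
  }
  expect_identical(run(), run())
})

test_that("sequence-panel flip rates produce the expected LD ladder", {
  cfg <- sim_config(
    seed = 12, n_founders = 400, founder_female_frac = 0.75,
    n_generations = 2, offspring_per_generation = 250, n_herds = 4,
    n_chromosomes = 1, snps_per_chromosome = 50, chromosome_length = 2e6,
    qtl = list(chrom = 1, start = 9e5, end = 1.05e6, effect = -1,
      target_freq = 0.3),
    seq_panel = list(window = c(6e5, 1.4e6), n_linked = 4,
      flip_rates = c(0, 0.02, 0.1, 0.2), n_independent = 4,
      missing_rate = 0, n_samples = 400)
  )
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  panel <- simulate_seq_panel(g, cfg)
  dip <- qtl_diplotype(g)
  ld <- haplotype_variant_ld(dip, panel, r2_floor = 0)
  linked_cols <- which(panel$variants$linked)
  r2 <- ld$r2[match(colnames(panel$geno)[linked_cols], ld$variant)]
  fr <- panel$variants$flip_rate[linked_cols]
  # zero-flip variant is a perfect proxy
  expect_equal(r2[which(fr == 0)], 1, tolerance = 1e-12)
  # r2 ordering matches the flip-rate ladder
  expect_equal(order(-r2), order(fr))
  # independent variants stay near zero
  indep <- ld$r2[match(
    colnames(panel$geno)[!panel$variants$linked], ld$variant
  )]
  expect_true(all(indep < 0.1))
})
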