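#' Simulate a multi-generation herd pedigree
#'
#' Builds a pedigree with founder animals followed by `n_generations`
#' breeding cycles. Each cycle produces `offspring_per_generation` calves by
#' mating a randomly drawn eligible sire (male, at least two years old at
#' calving) with a randomly drawn eligible dam (female, at least two years
#' old, at most one calving per year). Females inherit their dam's herd;
#' founder females are assigned herds uniformly. Breed fractions are drawn
#' for founders from a two-breed vocabulary (`HOL`, `SIM`) and averaged down
#' the pedigree.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` of class `twin_pedigree`, one row per animal in
#'   topological (parents-first) order, with columns `id`, `sire`, `dam`
#'   (integer ids, `NA` for unknown), `sex` (`"M"`/`"F"`), `birth_year`,
#'   `birth_month`, `herd`, `generation`, and breed fractions `breed_HOL`,
#'   `breed_SIM` summing to 1.
#' @examples
#' ped <- simulate_pedigree(sim_config(seed = 42, n_founders = 20,
#'   n_generations = 2, offspring_per_generation = 10))
#' head(ped)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1), {
    nf <- config$n_founders
    n_fem <- round(nf * config$founder_female_frac)
    if (n_fem < 1 || n_fem >= nf) {
      stop_twinqtl("impossible mating structure: need both founder sexes")
    }
    y0 <- min(config$years)
    sex <- rep("M", nf)
    sex[sample.int(nf, n_fem)] <- "F"
    founders <- data.frame(
      id = seq_len(nf), sire = NA_integer_, dam = NA_integer_,
      sex = sex,
      birth_year = y0 - sample(2:4, nf, replace = TRUE),
      birth_month = sample.int(12, nf, replace = TRUE),
      herd = sample.int(config$n_herds, nf, replace = TRUE),
      generation = 0L
    )
    frac <- sample(c(1, 0.5, 0), nf, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    founders$breed_HOL <- frac
    founders$breed_SIM <- 1 - frac

    ped <- founders
    n_years <- length(config$years)
    next_id <- nf + 1L
    active <- integer(0) # current dam cohort; calves once per cycle
    for (g in seq_len(config$n_generations)) {
      year <- config$years[min(g, n_years)]
      elig_f <- ped$id[ped$sex == "F" & ped$birth_year <= year - 2]
      elig_m <- ped$id[ped$sex == "M" & ped$birth_year <= year - 2]
      n_off <- config$offspring_per_generation
      if (length(elig_m) == 0) {
        stop_twinqtl("impossible mating structure: no eligible sires in cycle ", g)
      }
      if (length(elig_f) < n_off) {
        stop_twinqtl(
          "impossible mating structure: ", length(elig_f),
          " eligible dams for ", n_off, " calvings in cycle ", g
        )
      }
      # herd turnover: cull part of the cohort, fill with fresh heifers
      active <- intersect(active, elig_f)
      n_cull <- min(
        length(active), round(config$dam_replacement_rate * n_off)
      )
      if (n_cull > 0) active <- sample(active, length(active) - n_cull)
      fresh <- setdiff(elig_f, active)
      n_new <- n_off - length(active)
      if (n_new > 0) {
        active <- c(active, sample(fresh, min(n_new, length(fresh))))
      } else if (n_new < 0) {
        active <- sample(active, n_off)
      }
      dams <- sample(active)
      sires <- elig_m[sample.int(length(elig_m), n_off, replace = TRUE)]
      ids <- seq.int(next_id, next_id + n_off - 1L)
      off <- data.frame(
        id = ids, sire = sires, dam = dams,
        sex = sample(c("M", "F"), n_off, replace = TRUE),
        birth_year = year,
        birth_month = sample.int(12, n_off, replace = TRUE),
        herd = ped$herd[match(dams, ped$id)],
        generation = g
      )
      off$breed_HOL <- (ped$breed_HOL[match(sires, ped$id)] +
        ped$breed_HOL[match(dams, ped$id)]) / 2
      off$breed_SIM <- 1 - off$breed_HOL
      ped <- rbind(ped, off)
      next_id <- next_id + n_off
    }
    attr(ped, "seed") <- config$seed
    class(ped) <- c("twin_pedigree", "data.frame")
    ped
  })
}

#' Validate topological ordering of a pedigree
#'
#' Checks that every parent id appears before its offspring, that no animal
#' is its own ancestor, and that breed fractions sum to one.
#'
#' @param pedigree a pedigree `data.frame` (`id`, `sire`, `dam`, breed
#'   fraction columns).
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_pedigree <- function(pedigree) {
  pos <- seq_len(nrow(pedigree))
  idx_s <- match(pedigree$sire, pedigree$id)
  idx_d <- match(pedigree$dam, pedigree$id)
  if (any(!is.na(pedigree$sire) & is.na(idx_s)) ||
    any(!is.na(pedigree$dam) & is.na(idx_d))) {
    stop_twinqtl("pedigree refers to parents that are not listed")
  }
  if (any(idx_s >= pos, na.rm = TRUE) || any(idx_d >= pos, na.rm = TRUE)) {
    stop_twinqtl("pedigree is not in parents-first order")
  }
  bf <- grep("^breed_", names(pedigree))
  if (length(bf) > 0) {
    s <- rowSums(as.matrix(pedigree[, bf, drop = FALSE]))
    if (any(abs(s - 1) > 1e-9)) {
      stop_twinqtl("breed fractions must sum to 1")
    }
  }
  invisible(TRUE)
}
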