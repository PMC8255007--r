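#' Simulation configuration for the synthetic herd
#'
#' Bundles every parameter of the herd simulator: pedigree structure, marker
#' map, planted QTL, variance components, fixed-effect values and the
#' sequence-panel layout. The defaults reproduce the statistical conditions
#' of the study population: Table-3-scale variance components on the
#' 1/2-coded response, a 3.56% multiple-birth prevalence in binary mode, a
#' planted maternal haplotype at frequency 0.275, and a QTL window whose
#' share of the maternal genetic variance is about 16%.
#'
#' @param seed integer seed; recorded in all outputs.
#' @param n_founders number of founder animals (generation 0).
#' @param founder_female_frac fraction of founders that are female.
#' @param n_generations number of breeding cycles after the founders.
#' @param offspring_per_generation calves born per breeding cycle.
#' @param dam_replacement_rate fraction of the active dam cohort replaced by
#'   young females each breeding cycle (herd turnover; default 0.15, so a
#'   dam stays in production for about six years).
#' @param n_herds number of herds; every female is assigned one at birth.
#' @param years integer vector of calendar years; breeding cycles are mapped
#'   onto it cyclically.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length marker map:
#'   chromosomes, SNPs per chromosome, and chromosome length in bp.
#' @param recomb_rate per-bp, per-meiosis recombination rate (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param founder_pool_size number of distinct founder haplotypes per
#'   chromosome in the block-LD pool.
#' @param block_span span (bp) of an LD block in the founder pool.
#' @param variants_per_block distinct allele patterns per LD block.
#' @param qtl `NULL` for no planted QTL, else a list with elements `chrom`,
#'   `start`, `end` (bp bounds of the haplotype window), `effect` (additive
#'   effect of one haplotype copy on the dam's maternal value, response
#'   units) and `target_freq` (founder frequency of the focal haplotype).
#' @param variance_components a [variance_components()] object used as
#'   simulation truth.
#' @param fixed_effects list with per-level values for `parity` (length 5,
#'   parities 1..5+), `sexed` (no/yes), `season`
#'   (spring/summer/fall/winter), the `age_slope` per month of dam age, and
#'   the `intercept`.
#' @param phenotype_mode `"gaussian"` emits the latent value directly (the
#'   model is then exactly the linear mixed model assumed downstream);
#'   `"binary"` thresholds it into the 1/2 code.
#' @param prevalence target multiple-birth rate in binary mode; ignored if
#'   `binary_threshold` is given.
#' @param binary_threshold explicit latent threshold for code 2; `NULL`
#'   calibrates it to `prevalence` from the realized latent distribution.
#' @param embryo_transfer_rate fraction of records flagged as embryo
#'   transfer.
#' @param sexed_semen_rate fraction of inseminations with sexed semen.
#' @param seq_panel `NULL`, or a list with `window` (bp bounds `c(start,
#'   end)` inside the QTL chromosome), `n_linked` and `flip_rates` (linked
#'   variants copying the planted-haplotype indicator, one flip rate each,
#'   recycled), `n_independent` (variants drawn independently),
#'   `missing_rate`, `n_samples`, and `breeds` (label vocabulary).
#'
#' @return An object of class `sim_config` (validated list).
#' @seealso [simulate_pedigree()], [simulate_genotypes()],
#'   [simulate_phenotypes()], [simulate_seq_panel()]
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 120L,
                       founder_female_frac = 0.75,
                       n_generations = 4L,
                       offspring_per_generation = n_founders,
                       dam_replacement_rate = 0.15,
                       n_herds = 8L,
                       years = 2006:2018,
                       n_chromosomes = 1L,
                       snps_per_chromosome = 120L,
                       chromosome_length = 2e6,
                       recomb_rate = 1e-8,
                       founder_pool_size = 40L,
                       block_span = 1e5,
                       variants_per_block = 4L,
                       qtl = list(
                         chrom = 1L, start = 5e5, end = 5.7e5,
                         effect = -0.0226, target_freq = 0.275
                       ),
                       variance_components = reference_variance_components(),
                       fixed_effects = list(
                         intercept = 0.65,
                         parity = c(0.305, 0.356, 0.368, 0.374, 0.379),
                         sexed = c(no = 0.354, yes = 0.346),
                         season = c(
                           spring = 0.346, summer = 0.364,
                           fall = 0.354, winter = 0.351
                         ),
                         age_slope = 1e-4
                       ),
                       phenotype_mode = c("gaussian", "binary"),
                       prevalence = 0.0356,
                       binary_threshold = NULL,
                       embryo_transfer_rate = 0.01,
                       sexed_semen_rate = 0.053,
                       seq_panel = NULL) {
  phenotype_mode <- match.arg(phenotype_mode)
  cfg <- as.list(environment())
  counts <- c(
    n_founders, n_generations, n_herds, n_chromosomes,
    snps_per_chromosome, offspring_per_generation, founder_pool_size
  )
  if (any(counts <= 0)) stop_twinqtl("all counts must be > 0")
  if (founder_female_frac <= 0 || founder_female_frac >= 1) {
    stop_twinqtl("founder_female_frac must be in (0, 1)")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_twinqtl("target prevalence must be in (0, 1)")
  }
  stopifnot(inherits(variance_components, "variance_components"))
  if (!is.null(qtl)) {
    stopifnot(all(c("chrom", "start", "end", "effect", "target_freq")
    %in% names(qtl)))
    if (qtl$chrom < 1 || qtl$chrom > n_chromosomes) {
      stop_twinqtl("qtl chromosome outside the simulated map")
    }
    if (qtl$start < 1 || qtl$end > chromosome_length || qtl$start >= qtl$end) {
      stop_twinqtl("qtl window must lie inside one simulated chromosome")
    }
    if (qtl$target_freq <= 0 || qtl$target_freq >= 1) {
      stop_twinqtl("qtl target frequency must be in (0, 1)")
    }
  }
  fe <- fixed_effects
  stopifnot(
    length(fe$parity) == 5, length(fe$sexed) == 2, length(fe$season) == 4
  )
  if (!is.null(seq_panel)) {
    stopifnot(all(c("window", "n_linked") %in% names(seq_panel)))
    seq_panel$flip_rates <- seq_panel$flip_rates %||% 0.05
    seq_panel$n_independent <- seq_panel$n_independent %||% 0L
    seq_panel$missing_rate <- seq_panel$missing_rate %||% 0
    seq_panel$breeds <- seq_panel$breeds %||% c("HOL", "SIM", "OBV")
    cfg$seq_panel <- seq_panel
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config> seed", x$seed, "|", x$n_founders, "founders +",
    x$n_generations, "x", x$offspring_per_generation, "offspring |",
    x$n_chromosomes, "chr x", x$snps_per_chromosome, "SNPs |",
    if (is.null(x$qtl)) "no QTL" else
      sprintf(
        "QTL chr%d:%g-%g effect %g freq %g", x$qtl$chrom, x$qtl$start,
        x$qtl$end, x$qtl$effect, x$qtl$target_freq
      ),
    "\n"
  )
  invisible(x)
}
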