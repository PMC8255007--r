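# Readers/writers for the plain-text interchange formats of the pipeline.

#' Reported genome-wide significant markers
#'
#' The fifteen markers reported genome-wide significant (Bonferroni 5%,
#' 691,222 tests) for the maternal multiple-birth trait, shipped with the
#' package as a worked example for [bonferroni_significant()].
#'
#' @return `data.frame` with `chrom`, `pos`, `snp`, `alleles`, `freq`,
#'   `variance`, `p`.
#' @export
reported_gwas_hits <- function() {
  read.delim(
    system.file("extdata", "reported_gwas_hits.tsv", package = "twinqtl"),
    stringsAsFactors = FALSE
  )
}

#' @rdname pedigree_io
#' @export
write_pedigree_csv <- function(pedigree, path) {
  write.csv(as.data.frame(pedigree), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pedigree CSV input/output
#'
#' @param pedigree pedigree `data.frame`.
#' @param path file path.
#' @return The pedigree (reader) or the path, invisibly (writer).
#' @name pedigree_io
#' @export
read_pedigree_csv <- function(path) {
  ped <- read.csv(path, stringsAsFactors = FALSE)
  class(ped) <- c("twin_pedigree", "data.frame")
  ped
}

#' @rdname phenotype_io
#' @export
write_phenotypes_csv <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Birth-record CSV input/output
#'
#' @param records birth records `data.frame`.
#' @param path file path.
#' @return The records (reader) or the path, invisibly (writer).
#' @name phenotype_io
#' @export
read_phenotypes_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  class(rec) <- c("birth_records", "data.frame")
  rec
}

#' Write phased genotypes as VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` fields (`0|1` style), one
#' sample column per animal.
#'
#' @param phased a `phased_genotypes` object.
#' @param path output path (`.vcf`).
#' @return The path, invisibly.
#' @export
write_phased_vcf <- function(phased, path) {
  map <- phased$map
  gt <- matrix(
    paste(t(phased$H1), t(phased$H2), sep = "|"),
    nrow = nrow(map)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=twinqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", as.character(phased$ids)
    ), collapse = "\t")
  )
  body <- paste(
    map$chrom, map$pos, map$id, map$ref, map$alt, ".", ".", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Parses a VCF with phased `GT` fields back into a `phased_genotypes`
#' object (via the `vcfR` reader).
#'
#' @param path VCF path.
#' @return A `phased_genotypes` object.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE))) {
    stop_twinqtl("VCF contains unphased genotypes; phase first")
  }
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
  fix <- vcfR::getFIX(v)
  map <- data.frame(
    chrom = as.integer(fix[, "CHROM"]), pos = as.numeric(fix[, "POS"]),
    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      map = map, H1 = t(a1), H2 = t(a2),
      ids = colnames(gt)
    ),
    class = "phased_genotypes"
  )
}

#' Write a sequence panel as VCF
#'
#' Unphased `GT` with `./.` for missing calls.
#'
#' @param panel a `seq_panel`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_seq_panel_vcf <- function(panel, path) {
  v <- panel$variants
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(v), nrow(panel$geno))
  gn <- t(panel$geno)
  ok <- !is.na(gn)
  gt[ok] <- code[as.character(gn[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=twinqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(panel$geno)
    ), collapse = "\t")
  )
  body <- paste(
    v$chrom, v$pos, colnames(panel$geno), v$ref, v$alt, ".", ".", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sequence panel from a VCF
#'
#' @param path VCF path.
#' @param breeds optional `data.frame` (`id`, `breed`) of sample labels.
#' @return A `seq_panel` (families empty; attach with [panel_families()]).
#' @export
read_seq_panel_vcf <- function(path, breeds = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- rownames(gt)
  samples <- data.frame(id = colnames(gt), breed = NA_character_)
  if (!is.null(breeds)) {
    samples$breed <- breeds$breed[match(samples$id, breeds$id)]
  }
  structure(
    list(
      variants = data.frame(
        chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
        ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
      ),
      geno = geno, samples = samples,
      families = data.frame(
        child = integer(0), sire = integer(0), dam = integer(0)
      )
    ),
    class = "seq_panel"
  )
}

#' Write a PLINK-text (ped/map) mirror of phased genotypes
#'
#' @param phased a `phased_genotypes` object.
#' @param prefix output prefix (writes `<prefix>.ped` and `<prefix>.map`).
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(phased, prefix) {
  map <- phased$map
  writeLines(
    paste(map$chrom, map$id, 0, map$pos, sep = "\t"),
    paste0(prefix, ".map")
  )
  allele <- function(h, j) ifelse(h[, j] == 0, map$ref[j], map$alt[j])
  n <- length(phased$ids)
  geno_cols <- vapply(seq_len(nrow(map)), function(j) {
    paste(allele(phased$H1, j), allele(phased$H2, j))
  }, character(n))
  lines <- paste(
    1, phased$ids, 0, 0, 0, -9,
    apply(geno_cols, 1, paste, collapse = " ")
  )
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write a provenance file for a simulation output directory
#'
#' Records the seed and an MD5 hash of the serialized configuration, so any
#' output directory can be traced back to the exact configuration that
#' produced it.
#'
#' @param dir output directory.
#' @param config the [sim_config()] used.
#' @return Path of the provenance file, invisibly.
#' @export
write_provenance <- function(dir, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  path <- file.path(dir, "PROVENANCE.txt")
  writeLines(c(
    paste0("seed: ", config$seed),
    paste0("config_md5: ", hash),
    paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  ), path)
  invisible(path)
}
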