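#' Filter birth records for analysis
#'
#' Applies the phenotype-preparation rules in a fixed, auditable order:
#' embryo-transfer records are removed first; then all records from herds
#' with fewer than `min_herd_records` records (herd counts evaluated on the
#' post-embryo-transfer set); then, optionally, all records in herd-year
#' classes with fewer than `min_herd_year_records` records (herd-year counts
#' evaluated on the post-herd set). Leaving `min_herd_year_records` at
#' `NULL` reproduces the breeding-value dataset variant (no herd-year rule);
#' setting it to 5 reproduces the variance-component dataset variant.
#'
#' @param records a `data.frame` of birth records with at least `herd`,
#'   `year` and `embryo_transfer` columns.
#' @param min_herd_records minimum records per herd (default 260).
#' @param min_herd_year_records minimum records per herd-year class, or
#'   `NULL` to skip the rule.
#' @param drop_embryo_transfer remove embryo-transfer records first.
#' @return A list with `records` (the retained rows) and `report` (a
#'   `data.frame` counting input, removals per rule, and retained records).
#' @export
filter_records <- function(records, min_herd_records = 260,
                           min_herd_year_records = NULL,
                           drop_embryo_transfer = TRUE) {
  required <- c("herd", "year")
  missing_fields <- required[!required %in% names(records)]
  if (length(missing_fields) > 0) {
    stop_twinqtl(
      "records are missing field(s): ", paste(missing_fields, collapse = ", ")
    )
  }
  if (anyNA(records$herd) || anyNA(records$year)) {
    bad <- which(is.na(records$herd) | is.na(records$year))
    stop_twinqtl(
      "missing herd/year in record(s) ", paste(head(bad, 5), collapse = ", ")
    )
  }
  n_input <- nrow(records)

  n_et <- 0L
  if (drop_embryo_transfer && "embryo_transfer" %in% names(records)) {
    keep <- !records$embryo_transfer
    n_et <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }

  herd_n <- table(records$herd)
  small_herd <- names(herd_n)[herd_n < min_herd_records]
  keep <- !(as.character(records$herd) %in% small_herd)
  n_herd <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  n_hy <- 0L
  if (!is.null(min_herd_year_records)) {
    hy <- paste(records$herd, records$year, sep = ":")
    hy_n <- table(hy)
    small_hy <- names(hy_n)[hy_n < min_herd_year_records]
    keep <- !(hy %in% small_hy)
    n_hy <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }

  report <- data.frame(
    rule = c(
      "input", "embryo_transfer", "small_herd", "small_herd_year", "retained"
    ),
    n = c(n_input, n_et, n_herd, n_hy, nrow(records))
  )
  stopifnot(n_et + n_herd + n_hy + nrow(records) == n_input)
  list(records = records, report = report)
}

#' Multiple-birth rate
#'
#' Proportion of records with multiple-birth code 2.
#'
#' @param records birth records with a `code` column.
#' @return A single proportion.
#' @export
multiple_birth_rate <- function(records) {
  if (nrow(records) == 0) stop_twinqtl("no records")
  mean(records$code == 2)
}

#' Encode the model frame of the animal model
#'
#' Turns validated birth records into the response and factor columns of the
#' direct-maternal animal model. Level ordering is fixed: parity `1,2,3,4,5+`
#' (parities above 5 are capped into `5+`), season
#' `spring,summer,fall,winter`, sexed semen `no,yes` (missing flags default
#' to `no`, the reference level). Herd-year is the interaction of herd and
#' year. Every dam must appear in the pedigree.
#'
#' @param records birth records.
#' @param pedigree pedigree containing every calf and dam.
#' @return A `data.frame` of class `model_frame` with columns `code`
#'   (response), `parity`, `season`, `sexed_semen`, `herd_year` (factors),
#'   `age_months`, `calf`, `dam`; per-level observation counts are stored in
#'   `attr(, "level_counts")`.
#' @export
encode_model_frame <- function(records, pedigree) {
  missing_dams <- setdiff(unique(records$dam), pedigree$id)
  if (length(missing_dams) > 0) {
    stop_twinqtl(
      "dams absent from pedigree: ",
      paste(head(missing_dams, 10), collapse = ", ")
    )
  }
  if (any(records$parity < 1)) stop_twinqtl("parity must be >= 1")
  parity <- factor(
    ifelse(records$parity >= 5, "5+", as.character(records$parity)),
    levels = c("1", "2", "3", "4", "5+")
  )
  season <- factor(records$season, levels = season_levels())
  sexed <- records$sexed_semen
  sexed[is.na(sexed)] <- "no"
  sexed <- factor(sexed, levels = c("no", "yes"))
  herd_year <- factor(paste(records$herd, records$year, sep = ":"))
  mf <- data.frame(
    code = records$code, parity = parity, season = season,
    sexed_semen = sexed, herd_year = herd_year,
    age_months = records$age_months, calf = records$calf, dam = records$dam
  )
  counts <- rbind(
    data.frame(factor = "parity", level = levels(parity),
      n = as.integer(table(parity))),
    data.frame(factor = "sexed_semen", level = levels(sexed),
      n = as.integer(table(sexed))),
    data.frame(factor = "season", level = levels(season),
      n = as.integer(table(season)))
  )
  attr(mf, "level_counts") <- counts
  class(mf) <- c("model_frame", "data.frame")
  mf
}
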