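# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed: keeps derived seeds inside the 32-bit range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_twinqtl <- function(...) stop(..., call. = FALSE)

# Parse "chr:start-end" segment strings (1-based inclusive).
parse_segment <- function(segment) {
  if (is.list(segment)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(segment)))
    return(segment)
  }
  m <- regmatches(segment, regexec("^([^:]+):([0-9]+)-([0-9]+)$", segment))[[1]]
  if (length(m) != 4) {
    stop_twinqtl("segment must be 'chr:start-end', got '", segment, "'")
  }
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

# Mar-May spring, Jun-Aug summer, Sep-Nov fall, Dec-Feb winter.
season_from_month <- function(month) {
  c(
    "winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "fall", "fall", "fall", "winter"
  )[month]
}

season_levels <- function() c("spring", "summer", "fall", "winter")
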