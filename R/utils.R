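# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounding convention used for every printed percentage in the package's
#' tables: ties go up (`0.05 -> 0.1`), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a denominator, display-rounded
#'
#' The single reporting path used by coverage, benefit and regional tables:
#' `100 * covered / denominator`, rounded half-up to `digits` decimals.
#' Full precision is never stored in the `pct` column; the raw counts are.
#'
#' @param covered numeric vector of covered counts (persons, cells, km2).
#' @param denominator scalar or vector denominator under the table's stated
#'   convention.
#' @param digits decimal places for display (default 1, the conventional
#'   one-decimal style of coverage tables).
#' @return numeric vector of percentages; `NA` where the denominator is 0.
#' @export
pct_round <- function(covered, denominator, digits = 1) {
  n <- max(length(covered), length(denominator))
  covered <- rep_len(covered, n)
  denominator <- rep_len(denominator, n)
  out <- round_half_up(100 * covered / denominator, digits)
  out[denominator == 0] <- NA_real_
  as.numeric(out)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed for a sub-generator; keeps values in 32-bit range.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7 + offset * 104729) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
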