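`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' The global RNG state is saved, the seed set, the code evaluated, and the
#' state restored. A `NULL` seed leaves the current RNG stream untouched so
#' callers get ordinary (non-reproducible) randomness.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Format a percentage for narrative text
#'
#' Round-half-even to two decimals, then trim trailing zeros (and a bare
#' decimal point), so 82.931 -> "82.93" and 70.402 -> "70.4".
#' @noRd
format_pct <- function(x) {
  s <- formatC(round(x, 2), format = "f", digits = 2)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Format a parameter value for narrative text (full precision, no sci notation)
#' @noRd
format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
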