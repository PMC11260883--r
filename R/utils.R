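# Characters treated as missing for coverage, trimming and haplotype length;
# IUPAC partial ambiguities (R, Y, ...) count as present here but are never
# comparable sites for distances.
MISSING_CHARS <- c("-", "N", "?")

#' @keywords internal
is_missing_char <- function(x) x %in% MISSING_CHARS

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs under the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Round half away from zero (printed-report convention), unlike base round()'s
# round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a sub-seed for a named pipeline stage, staying inside 32-bit range.
stage_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
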