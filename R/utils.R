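# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for all published-style tables: ties go away from
#' zero (so 0.05 -> 0.1), unlike [base::round()]'s banker's rounding.
#' A tiny epsilon guards against binary representation error on exact ties
#' (values here are percentages, magnitude <= 100).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.05, -0.05, 2.345), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Deterministic per-unit sub-seed so adding records never perturbs earlier
# ones. Kept below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
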