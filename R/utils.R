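#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the convention of
#' the printed toxicity tables (base `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalize Unicode minus signs (U+2212, U+2013) to ASCII hyphen-minus so
# tables copied from typeset sources parse as numbers.
normalize_minus <- function(x) {
  gsub("−|–", "-", x)
}

# Deterministic fan-out of one user seed into per-stage seeds. Keeps every
# derived seed a valid 32-bit R integer.
split_seed <- function(seed, n = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  base <- as.double(abs(as.integer(seed)))
  # multiplicative congruential step, modulus below 2^31
  m <- 2147483629
  out <- integer(n)
  s <- (base * 48271 + 11) %% m
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11) %% m
    out[i] <- as.integer(s)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_duotox <- function(..., class) {
  stop(structure(
    class = c(class, "duotox_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
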