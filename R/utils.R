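# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a root seed and a counter.
# Keeps everything below .Machine$integer.max; exact in double arithmetic
# (products stay well under 2^53).
derive_seed <- function(root_seed, counter) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.numeric(counter), length(counter) == 1L)
  as.integer((abs(root_seed) * 48271 + counter * 16807 + 12345) %% 2147483647)
}

# Polynomial rolling hash of a character scalar, returned as 8 hex digits.
# Used only to stamp provenance files; not cryptographic.
string_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_probability <- function(x) is_scalar_number(x) && x >= 0 && x <= 1

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Standard error of a mean; NA for n < 2 (reported missing, never 0).
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
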