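## Internal helpers: deterministic sub-stream seeding, a small config hash,
## and truncated-normal draws.

#' Derive a deterministic sub-stream seed
#'
#' Mixes a master seed with one or more integer indices through a Lehmer-style
#' recurrence modulo 2^31 - 1. Used so that every run / subject / replicate
#' gets its own reproducible RNG stream: adding runs or replicates never
#' perturbs draws belonging to earlier ones.
#'
#' @param seed master integer seed.
#' @param ... integer indices (e.g. stream id, run index, subject index).
#' @return a positive integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (k in c(...)) {
    # 48271 * (m - 1) < 2^53, so double arithmetic stays exact
    h <- (h * 48271 + as.double(k) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

## 32-bit FNV-1a over a character string, done in 16-bit halves so products
## stay below 2^53. Returns an 8-hex-digit string; used to stamp pipeline
## outputs with the configuration they came from.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## xor of two nonneg doubles interpreted as 32-bit words
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.double(hi) * 65536 + as.double(lo)
}

## Hash a configuration list via its canonical JSON rendering.
config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

## Truncated normal by rejection; the truncation intervals used here
## (body-size ranges ~2 sd wide) keep acceptance rates high.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  stopifnot(lower < upper, sd >= 0)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}
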