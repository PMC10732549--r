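# Internal helpers shared across modules.

# 32-bit FNV-1a over the UTF-8 bytes of a string, returned as a double in
# [0, 2^32). Doubles overflow past 2^53, so the multiply is split into
# 16-bit halves.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor64(h, b)
    hi <- floor(h / two16)
    lo <- h - hi * two16
    h <- ((hi * p) %% two16) * two16 + lo * p
    h <- h %% two32
  }
  h
}

# xor of two non-negative doubles < 2^32 (R's bitwXor only covers ints)
bitwXor64 <- function(a, b) {
  two16 <- 65536
  ahi <- floor(a / two16); alo <- a - ahi * two16
  bhi <- floor(b / two16); blo <- b - bhi * two16
  bitwXor(as.integer(ahi), as.integer(bhi)) * two16 +
    bitwXor(as.integer(alo), as.integer(blo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}
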