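# Internal helpers: RNG scoping and a small content digest.

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state (and kind) afterwards so library calls never perturb user code.
with_seed <- function(seed, expr, kind = "Mersenne-Twister") {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind[1:2]))
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  suppressWarnings(RNGkind(kind))
  set.seed(seed)
  expr
}

# 32-bit xor / modular multiply on doubles holding unsigned 32-bit values
# (base bitwXor only accepts values < 2^31).
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 2^16), as.integer(b %/% 2^16)) * 2^16 +
    bitwXor(as.integer(a %% 2^16), as.integer(b %% 2^16))
}

mulmod32 <- function(h, m) {
  lo <- h %% 2^16
  hi <- h %/% 2^16
  (lo * m + ((hi * m) %% 2^16) * 2^16) %% 2^32
}

# FNV-1a 32-bit over a character scalar, returned as 8-digit hex. Used to
# fingerprint a herd so estimate matrices can be matched to the population
# they were drawn from.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  # h is a double holding an unsigned 32-bit value; format in two halves
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
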