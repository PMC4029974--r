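#' Portable linear congruential random generator
#'
#' All randomness in the package (layout initialisation, synthetic dataset
#' generation) flows through this small, fully documented generator so that
#' results are bit-reproducible and the recipe is portable to any language:
#'
#'   state_{n+1} = (1664525 * state_n + 1013904223) mod 2^32
#'
#' (the Numerical Recipes LCG constants). Uniform deviates are
#' `(state + 0.5) / 2^32`, strictly inside (0, 1). The arithmetic stays below
#' 2^53 so plain double precision is exact.
#'
#' @param seed integer seed; reduced modulo 2^32.
#' @return a function `f(n)` returning `n` uniforms in (0, 1); the generator
#'   state advances with each call.
#' @examples
#' r <- lcg_rng(42)
#' r(3)
#' @export
lcg_rng <- function(seed) {
  state <- as.numeric(seed) %% 4294967296
  function(n = 1L) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (1664525 * state + 1013904223) %% 4294967296
      out[i] <- (state + 0.5) / 4294967296
    }
    out
  }
}

# FNV-1a 32-bit hash over the UTF-8 bytes of a string. Used to fingerprint
# dataset content in shared session payloads (collaborators loading a session
# against a different dataset get a hard error instead of a silently wrong
# view). Multiplication is split into 16-bit halves to stay exact in doubles.
fnv1a32 <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor for doubles holding 32-bit unsigned values (bitwXor needs < 2^31)
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(hi_a, hi_b) * 65536 + bitwXor(lo_a, lo_b)
}
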