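# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over a raw vector, in double arithmetic split into 16-bit
# halves so intermediate products stay exactly representable.
fnv1a32 <- function(bytes) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(bytes)) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# xor of a 32-bit value (double) with a byte
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2^31
  hi <- (h - lo) / 2^31
  x <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2^31 + x
}
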