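# Small internal helpers.

# Stable content hash (FNV-1a, 64-bit arithmetic done in two 16-bit
# halves to stay in double precision) over R's serialization of `x`.
# Used to fingerprint parameter sets, fibrosis maps and run configs.
raHash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  raw <- as.integer(raw[-seq_len(14L)])  # drop header (R version stamp)
  h <- 0x811c9dc5
  for (b in raw) {
    # xor only touches the low byte since b < 256
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # h <- h * 16777619 mod 2^32, in pieces to avoid integer overflow
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# deterministic uniforms from an integer seed without touching the
# caller's RNG stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, nm = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", nm), call. = FALSE)
  invisible(x)
}
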