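`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' FNV-1a hash of a character vector
#'
#' Stable 32-bit hash used to fingerprint feature-bank registries so a
#' serialized model can detect a schema mismatch at predict time.
#'
#' @param x character vector; elements are concatenated with `"\n"`.
#' @return hex string of the 32-bit FNV-1a digest.
#' @export
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h in double space
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime, split into 16-bit halves so
    # every intermediate product stays exactly representable in a double
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# deterministic child seed derived from a user seed and a stream label,
# kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 69069 + sum(utf8ToInt(stream))) %% 2147483647)
}

# run expr with a local RNG state seeded from `seed` (restores state on exit)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
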