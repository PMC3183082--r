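#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = leave the
# global stream alone). Restores .Random.seed afterwards so callers' streams
# are not perturbed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a stage tag.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- fnv1a32(paste0(as.integer(seed), ":", tag))
  as.integer(h %% 2147483587)
}

# 32-bit FNV-1a hash of a character scalar, returned as a double in [0, 2^32).
# Used for provenance stamps and sub-seed derivation only.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit overflow multiply by the FNV prime, in 16-bit halves so all
    # intermediates stay inside double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

config_hash <- function(x) {
  sprintf("%08x", fnv1a32(paste(deparse(x), collapse = "\n")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}
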