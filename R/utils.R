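# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates `expr`, and restores the
#' state on exit.  When `seed` is `NULL` the expression runs under the
#' current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialise a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed, a stream label and an
# index.  All pipeline randomness flows from one top-level seed split into
# named substreams (scene, chemistry, splits, ...) so that components stay
# reproducible in isolation.  Kept strictly below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  h <- fnv1a32(paste(stream, index, sep = ":"))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# 31-bit polynomial rolling hash of a character string; pure-R, used for
# substream derivation and provenance fingerprints of configuration objects.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

# Short provenance fingerprint of an arbitrary R object.
config_hash <- function(x) {
  sprintf("%08x", fnv1a32(paste(deparse(x), collapse = "")))
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_olivescan <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "olivescan_error")))
}
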