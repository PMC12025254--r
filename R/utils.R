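#' @keywords internal
"_PACKAGE"

# Stage-scoped seed derivation: one user-facing seed fans out to per-stage
# streams so stages stay independently reproducible. Constants are the
# classic Knuth LCG multiplier and an FNV-style fold of the tag; arithmetic
# kept in doubles below 2^31.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% 2147483629 + 1)
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# FNV-1a over the serialized object; returned as 8-hex-digit string.
# Used to fingerprint configurations in metric tables and run manifests.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)]) # drop header
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
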