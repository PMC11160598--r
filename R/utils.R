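# Internal helpers shared across modules.

# Canonical (lexicographic) ordering of an unordered ID pair, vectorised.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tibble(
    og_a = ifelse(swap, b, a),
    og_b = ifelse(swap, a, b)
  )
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Derive a stage-specific substream seed from one global integer seed, so
# that each pipeline stage is independently reproducible. Kept < 2^31.
substream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Minimal union-find over character IDs (used to merge reference complexes
# that share members into leakage groups).
uf_new <- function(ids) {
  env <- new.env(parent = emptyenv())
  env$parent <- setNames(ids, ids)
  env
}

uf_find <- function(uf, x) {
  while (uf$parent[[x]] != x) {
    uf$parent[[x]] <- uf$parent[[uf$parent[[x]]]]
    x <- uf$parent[[x]]
  }
  x
}

uf_union <- function(uf, x, y) {
  rx <- uf_find(uf, x)
  ry <- uf_find(uf, y)
  if (rx != ry) uf$parent[[max(rx, ry)]] <- min(rx, ry)
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
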