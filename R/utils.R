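# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit seed derived from a base seed and an individual id,
# independent of query ordering.
derive_seed <- function(seed, id) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271) %% m
  as.double(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
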