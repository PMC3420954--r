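# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic child seed for a named pipeline substream, so stages
# can be re-run in isolation while all randomness flows from one root seed.
substream_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- utf8ToInt(label)
  # small polynomial hash folded into [0, 2^31 - 2]
  acc <- as.double(seed %% 2147483647)
  for (k in h) acc <- (acc * 31 + k) %% 2147483647
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
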