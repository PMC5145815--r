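# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 32-bit string hash (polynomial rolling hash, exact in
## doubles). Used to derive per-sample RNG streams and order-independent
## CV folds from ids, never from row positions.
str_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## Seed for a named sub-stream of a master seed; always < 2^31.
derive_seed <- function(master, key) {
  str_hash(paste0(format(master, scientific = FALSE), ":", key))
}

## Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
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

## Zero-truncated Poisson sampler by inversion.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

stop_ml <- function(...) stop(sprintf(...), call. = FALSE)
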