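# Internal helpers: memoization cache and deterministic random streams.

.molhitl_cache <- new.env(parent = emptyenv())

cache_get <- function(store, key) {
  env <- .molhitl_cache[[store]]
  if (is.null(env)) return(NULL)
  env[[key]]
}

cache_set <- function(store, key, value) {
  if (is.null(.molhitl_cache[[store]]))
    .molhitl_cache[[store]] <- new.env(parent = emptyenv())
  assign(key, value, envir = .molhitl_cache[[store]])
  invisible(value)
}

cache_clear <- function() {
  rm(list = ls(.molhitl_cache), envir = .molhitl_cache)
  invisible(NULL)
}

# Counter-based uniform and normal draws: reproducible across platforms and
# independent of R's global RNG state. `seed` selects the stream, `idx` the
# position within it.
runif_stream <- function(seed, idx) {
  cpp_hash_unif(as.double(seed), as.double(idx))
}

rnorm_stream <- function(seed, idx) {
  stats::qnorm(runif_stream(seed, idx))
}

# seeded permutation / weighted sampling built on the same streams
sample_stream <- function(n, size, seed, replace = FALSE, prob = NULL) {
  if (size == 0L) return(integer(0))
  if (replace) {
    u <- runif_stream(seed, seq_len(size))
    if (is.null(prob)) return(pmin(floor(u * n) + 1L, n))
    cw <- cumsum(prob) / sum(prob)
    return(findInterval(u, cw, left.open = TRUE) + 1L)
  }
  if (is.null(prob)) {
    # seeded permutation via random keys
    ord <- order(runif_stream(seed, seq_len(n)))
    return(ord[seq_len(min(size, n))])
  }
  # weighted without replacement (Efraimidis-Spirtsas keys)
  u <- runif_stream(seed, seq_len(n))
  keys <- ifelse(prob > 0, u^(1 / prob), -Inf)
  ord <- order(keys, decreasing = TRUE)
  ord[seq_len(min(size, sum(prob > 0)))]
}

# derive a child seed (kept within 32-bit integer range)
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 69069 + as.double(abs(p)) + 1) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_molhitl <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
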