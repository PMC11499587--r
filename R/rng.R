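# Seeded named substreams. All randomness in the package flows from a
# single integer seed through stream names, so adding draws to one stage
# never perturbs another, and identical (config, seed) is bit-reproducible.

sub_seed <- function(seed, stream) {
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147480009)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# A resumable uniform stream: each call continues where the previous left
# off, without touching the global RNG state observed by callers.
make_rng <- function(seed, stream) {
  state <- local({
    with_seed(sub_seed(seed, stream), get(".Random.seed", envir = globalenv()))
  })
  function(n, lo = 0, hi = 1) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    out <- runif(n, lo, hi)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    out
  }
}

rpois_seeded <- function(seed, stream, n, lambda) {
  with_seed(sub_seed(seed, stream), rpois(n, lambda))
}

sample_classes <- function(seed, stream, n, probs) {
  with_seed(sub_seed(seed, stream),
            sample.int(length(probs), n, replace = TRUE, prob = probs))
}

# k distinct ids from 1..n
sample_ids <- function(seed, stream, n, k) {
  if (k <= 0) return(integer(0))
  with_seed(sub_seed(seed, stream), sample.int(n, k))
}
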