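# small shared helpers

# let data.table's [ syntax (.N, by=) work from this package's namespace
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_fmt("%s must be a probability in [0, 1]", what)
  invisible(p)
}

# normalize nonnegative weights to a probability vector
normalize_weights <- function(w, what = "weights") {
  if (anyNA(w) || any(w < 0)) stop_fmt("%s must be nonnegative", what)
  s <- sum(w)
  if (s <= 0) stop_fmt("%s must have positive total mass", what)
  w / s
}

# Deterministic per-agent RNG stream seed. Mixes the run seed with the agent
# id so results do not depend on agent iteration order. All arithmetic stays
# below 2^53 so it is exact in doubles; result is a valid 32-bit seed.
agent_stream_seed <- function(seed, agent_id) {
  x <- (abs(seed) %% 2147483647) + agent_id
  x <- (x * 69069 + 1) %% 2147483647
  x <- (x * 69069 + 12345) %% 2147483647
  as.integer(x)
}

# run code with a local RNG state (restore the caller's state afterwards)
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# sample.int with probabilities, tolerant of length-1 pools
sample_idx <- function(n, size, prob = NULL) {
  if (n == 1L) return(rep.int(1L, size))
  sample.int(n, size, replace = TRUE, prob = prob)
}
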