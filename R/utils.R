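# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 32-bit sub-seed from a master seed and an index.
sub_seed <- function(seed, i) {
  (as.integer(seed) * 1103L + as.integer(i) * 12347L) %% 2147483563L
}

stopifnot_scalar_prob <- function(x, name, open_left = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!lo_ok || x > 1)
    stop(sprintf("`%s` must lie in %s0, 1]", name,
                 if (open_left) "(" else "["), call. = FALSE)
  invisible(x)
}

# Unordered sample-pair index pairs (i < j) for n samples.
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}
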