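# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Uniform random unit vectors in k dimensions (rows of the returned matrix).
random_unit_vectors <- function(n, k) {
  z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
  z / sqrt(rowSums(z^2))
}
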