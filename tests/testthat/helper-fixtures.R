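# Shared fixtures, built in code.

as_mat <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_unit_vectors <- function(n, k) {
  z <- matrix(stats::rnorm(n * k), n, k)
  z / sqrt(rowSums(z^2))
}

# 2x2 toy with eigenvalues 0.03 (along [1,1]/sqrt2) and 0.01.
toy_G2 <- function() {
  g_matrix(matrix(c(0.02, 0.01, 0.01, 0.02), 2,
                  dimnames = list(c("a", "b"), c("a", "b"))),
           n_families = 50)
}

# 3x3 positive-definite toy with distinct eigenvalues.
toy_G3 <- function() {
  m <- matrix(c(0.030, 0.010, 0.004,
                0.010, 0.020, 0.006,
                0.004, 0.006, 0.012), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g_matrix(m, n_families = 40)
}

# random PSD g_matrix via crossprod (independent of simulate_G)
random_psd_G <- function(k, seed) {
  with_seed(seed, {
    a <- matrix(stats::rnorm(k * k), k)
    g_matrix(crossprod(a) / k * 0.01, n_families = 50)
  })
}

# brute-force inverse via cofactor expansion, k <= 3 (independent oracle)
cofactor_inverse <- function(m) {
  k <- nrow(m)
  if (k == 1) return(matrix(1 / m[1, 1], 1, 1))
  cof <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    minor <- m[-i, -j, drop = FALSE]
    detm <- if (k == 2) minor[1, 1] else
      minor[1, 1] * minor[2, 2] - minor[1, 2] * minor[2, 1]
    cof[i, j] <- (-1)^(i + j) * detm
  }
  detm_full <- sum(m[1, ] * cof[1, ])
  t(cof) / detm_full
}

# a small default synthetic world shared across tests (built once)
shared_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_database(sim_config(
        n_species = 6, studies_per_species = 2, seed = 101))
    cache
  }
})
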