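test_that("mean-scaling divides by the outer product of trait means", {
  expect_equal(unclass(mean_scale_covariance(matrix(4), 2))[1, 1], 1)
  expect_equal(as_mat(mean_scale_covariance(diag(2), c(1, 1))), diag(2),
               ignore_attr = TRUE)
  raw <- matrix(c(0.08, 0.02, 0.02, 0.18), 2)
  out <- mean_scale_covariance(raw, c(2, 3))
  expect_equal(as_mat(out),
               matrix(c(0.02, 0.02 / 6, 0.02 / 6, 0.02), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(mean_scale_covariance(raw, c(2, 0)), "non-positive mean")
  expect_error(
    mean_scale_covariance(
      matrix(c(1, 0, 0, 1), 2, dimnames = list(c("x", "y"), c("x", "y"))),
      c(1, -1)),
    "trait y")
})

test_that("evolvability along directions matches hand eigenvalues", {
  G <- toy_G2()
  expect_equal(evolvability_along(G, c(1, 0)), 0.02)
  expect_equal(evolvability_along(G, c(1, 1) / sqrt(2)), 0.03)
  expect_equal(evolvability_along(G, c(1, -1) / sqrt(2)), 0.01)
  # label-aware reordering
  expect_equal(evolvability_along(G, c(b = 1, a = 0)), 0.02)
  expect_error(evolvability_along(G, c(x = 1, y = 0)), "labels")
  expect_warning(evolvability_along(G, c(2, 0)), "normalized")
})

test_that("conditional evolvability matches the cofactor-inverse oracle", {
  G <- toy_G2()
  expect_equal(conditional_evolvability_along(G, c(1, 0)), 0.015)
  # along an eigenvector c equals e
  expect_equal(conditional_evolvability_along(G, c(1, 1) / sqrt(2)), 0.03,
               tolerance = 1e-12)
  # diagonal G: no correlations, no constraint
  Gd <- g_matrix(diag(c(0.05, 0.01, 0.2)))
  expect_equal(conditional_evolvability_along(Gd, c(0, 1, 0)), 0.01)
  # singular matrix is a hard error, not a silent pseudo-inverse
  Gs <- g_matrix(matrix(c(1, 1, 1, 1), 2) * 0.01)
  expect_error(conditional_evolvability_along(Gs, c(1, 0)), "singular|ill")
  # brute-force oracle at k = 3
  G3 <- toy_G3()
  Gi <- cofactor_inverse(as_mat(G3))
  for (v in list(c(1, 0, 0), c(1, 1, 1) / sqrt(3), c(2, -1, 0.5))) {
    u <- v / sqrt(sum(v^2))
    expect_equal(conditional_evolvability_along(G3, u),
                 1 / drop(t(u) %*% Gi %*% u), tolerance = 1e-10)
    expect_equal(evolvability_along(G3, u),
                 drop(t(u) %*% as_mat(G3) %*% u), tolerance = 1e-10)
  }
})

test_that("matrix summary gives trace mean, eigen extremes, MC mean c", {
  G <- toy_G2()
  s <- matrix_summary(G, mc_samples = 20000, seed = 1)
  expect_equal(s$e_mean, 0.02)
  expect_equal(s$e_min, 0.01)
  expect_equal(s$e_max, 0.03)
  expect_equal(s$eigenvalues, c(0.03, 0.01))
  # ordering invariant e_min <= c_mean <= e_mean <= e_max
  expect_true(s$e_min <= s$c_mean && s$c_mean <= s$e_mean)
  # isotropy: all summaries collapse
  si <- matrix_summary(g_matrix(diag(2) * 0.004), mc_samples = 500, seed = 1)
  expect_equal(unlist(si[c("e_mean", "c_mean", "e_min", "e_max")]),
               rep(0.004, 4), ignore_attr = TRUE, tolerance = 1e-12)
  # singular matrix: c undefined, others intact
  Gs <- g_matrix(matrix(c(1, 1, 1, 1), 2) * 0.01)
  ss <- matrix_summary(Gs, mc_samples = 100, seed = 1)
  expect_true(is.na(ss$c_mean))
  expect_equal(ss$e_mean, 0.01)
})

test_that("eigen directions are descending, sign-fixed, orthonormal", {
  ed <- eigen_directions(toy_G2())
  expect_equal(ed$values, c(0.03, 0.01))
  expect_equal(abs(ed$vectors[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # largest-magnitude coefficient positive
  expect_true(all(apply(ed$vectors, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_equal(crossprod(ed$vectors), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # diagonal matrix: axis vectors ordered by diagonal
  edd <- eigen_directions(diag(c(0.1, 0.3, 0.2)))
  expect_equal(edd$values, c(0.3, 0.2, 0.1))
  expect_equal(edd$vectors[, 1], c(0, 1, 0), ignore_attr = TRUE)
  # eigenvalue sum conserves the trace
  G3 <- toy_G3()
  expect_equal(sum(eigen_directions(G3)$values), sum(diag(as_mat(G3))))
})

test_that("divergence projection is the quadratic form in D", {
  G <- toy_G2()
  D <- g_matrix(3 * as_mat(G))
  expect_equal(project_divergence(D, c(1, 1) / sqrt(2)), 0.09)
  expect_equal(project_divergence(D, c(1, 0)), 0.06)
  # rotation invariance: sum over any orthonormal basis equals the trace
  Q <- qr.Q(qr(matrix(c(1, 2, 2, -1), 2)))
  expect_equal(project_divergence(D, Q[, 1]) + project_divergence(D, Q[, 2]),
               sum(diag(as_mat(D))), tolerance = 1e-12)
})

test_that("c(v) <= e(v) bounded by eigen extremes over random directions", {
  for (seed in 1:3) {
    G <- random_psd_G(3, seed)
    s <- matrix_summary(G, mc_samples = 2000, seed = seed)
    U <- with_seed(seed + 100, random_unit_vectors(200, 3))
    for (i in seq_len(nrow(U))) {
      e <- evolvability_along(G, U[i, ])
      cv <- conditional_evolvability_along(G, U[i, ])
      expect_true(cv <= e + 1e-12)
      expect_true(e <= s$e_max + 1e-12 && e >= s$e_min - 1e-12)
    }
    # equality exactly at eigenvectors
    V <- eigen_directions(G)$vectors
    for (j in 1:3)
      expect_equal(conditional_evolvability_along(G, V[, j]),
                   evolvability_along(G, V[, j]), tolerance = 1e-10)
  }
})

test_that("mean evolvability over random directions converges to trace/k", {
  G <- toy_G3()
  U <- with_seed(11, random_unit_vectors(1e5, 3))
  e <- rowSums((U %*% as_mat(G)) * U)
  mc_se <- stats::sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - sum(diag(as_mat(G))) / 3), 3 * mc_se)
})

test_that("e and c are invariant to simultaneous trait permutation", {
  G3 <- toy_G3()
  perm <- c(3, 1, 2)
  Gp <- g_matrix(as_mat(G3)[perm, perm])
  v <- c(0.5, -0.3, 0.8); v <- v / sqrt(sum(v^2))
  expect_equal(evolvability_along(Gp, v[perm]), evolvability_along(G3, v))
  expect_equal(conditional_evolvability_along(Gp, v[perm]),
               conditional_evolvability_along(G3, v))
})

test_that("square CSV round trip preserves matrices and flags asymmetry", {
  G <- toy_G3()
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(G, f)
  G2 <- read_matrix_csv(f, n_families = 40)
  expect_equal(as_mat(G2), as_mat(G), tolerance = 1e-12)
  expect_equal(attr(G2, "n_families"), 40)
  # small asymmetry averaged with a message; large asymmetry rejected
  m <- as_mat(G); m[1, 2] <- m[1, 2] * (1 + 1e-9)
  utils::write.csv(m, f, row.names = TRUE)
  expect_message(read_matrix_csv(f), "asymmetry")
  m[1, 2] <- m[1, 2] * 2
  utils::write.csv(m, f, row.names = TRUE)
  expect_error(read_matrix_csv(f), "asymmetric")
})
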