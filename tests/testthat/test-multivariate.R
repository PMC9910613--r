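toy_case <- function(alpha = 3, P = TRUE) {
  G <- toy_G3()
  D <- g_matrix(alpha * as_mat(G))
  attr(D, "n_pops") <- 10
  case_study("toy", G, D,
             P = if (P) g_matrix(as_mat(G) / 0.3) else NULL,
             species = "sp1", n_pops = 10)
}

test_that("case construction enforces matched traits and k >= 3", {
  expect_s3_class(toy_case(), "qg_case")
  G <- toy_G3()
  D2 <- g_matrix(as_mat(G)[1:2, 1:2])
  expect_error(case_study("x", G, D2), "trait sets differ")
  expect_error(case_study("x", g_matrix(as_mat(G)[1:2, 1:2]), D2),
               ">= 3 traits")
})

test_that("direction sets are orthonormal and selector-correct", {
  case <- toy_case()
  V0 <- direction_set(case, "original")
  expect_equal(V0, diag(3), ignore_attr = TRUE)
  for (w in c("G_eigen", "D_eigen", "P_eigen")) {
    V <- direction_set(case, w)
    expect_equal(crossprod(V), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(direction_set(case, "G_eigen"),
               eigen_directions(case$G)$vectors)
  expect_error(direction_set(toy_case(P = FALSE), "P_eigen"), "no P-matrix")
})

test_that("proportional matrices give slope 1, r2 1, intercept log alpha", {
  case <- toy_case(alpha = 3)
  for (w in c("original", "G_eigen", "D_eigen", "P_eigen")) {
    r <- case_regression(case, w)
    expect_equal(r$slope, 1, tolerance = 1e-10)
    expect_equal(r$r2, 1, tolerance = 1e-10)
    expect_equal(r$intercept, log(3), tolerance = 1e-10)
  }
  # conditional evolvability equals evolvability along G eigenvectors
  rc <- case_regression(case, "G_eigen", conditional = TRUE)
  expect_equal(rc$slope, 1, tolerance = 1e-10)
  expect_equal(rc$r2, 1, tolerance = 1e-10)
})

test_that("power-law matrices give the exponent as slope on G directions", {
  G <- toy_G3()
  ed <- eigen_directions(G)
  D <- g_matrix(ed$vectors %*% diag(ed$values^2) %*% t(ed$vectors),
                sym_tol = 1e-8)
  case <- case_study("pw", G, D, species = "sp1", n_pops = 10)
  r <- case_regression(case, "G_eigen")
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$r2, 1, tolerance = 1e-10)
})

test_that("case regression matches a closed-form OLS oracle", {
  case <- toy_case()
  # break proportionality so the fit is non-trivial
  Dm <- as_mat(case$D); Dm[1, 1] <- Dm[1, 1] * 2
  case$D <- g_matrix(Dm, sym_tol = 1e-8)
  r <- case_regression(case, "original")
  x <- log(diag(as_mat(case$G))); y <- log(diag(Dm))
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(r$slope, b, tolerance = 1e-10)
  expect_equal(r$intercept, a, tolerance = 1e-10)
  # slope invariant to scaling D; intercept shifts by log of the factor
  case2 <- case; case2$D <- g_matrix(10 * Dm, sym_tol = 1e-8)
  r2 <- case_regression(case2, "original")
  expect_equal(r2$slope, r$slope, tolerance = 1e-12)
  expect_equal(r2$intercept, r$intercept + log(10), tolerance = 1e-10)
})

test_that("G resampling is seeded, unbiased, and inflates the lead eigenvalue", {
  G <- toy_G3()
  d1 <- resample_G(G, iters = 5, seed = 3)
  d2 <- resample_G(G, iters = 5, seed = 3)
  expect_identical(d1, d2)
  d3 <- resample_G(G, iters = 5, seed = 4)
  expect_false(identical(d1, d3))
  draws <- resample_G(G, iters = 2000, seed = 5, n_families = 12)
  arr <- simplify2array(draws)
  mean_mat <- apply(arr, 1:2, mean)
  se_mat <- apply(arr, 1:2, stats::sd) / sqrt(length(draws))
  expect_true(all(abs(mean_mat - as_mat(G)) <= 3 * se_mat + 1e-12))
  lead <- vapply(draws, function(m)
    max(eigen(m, only.values = TRUE)$values), numeric(1))
  expect_gt(mean(lead), max(eigen(as_mat(G), only.values = TRUE)$values))
  expect_warning(resample_G(G, iters = 2, seed = 1, n_families = 3),
                 "singular")
  bad <- g_matrix(matrix(c(0.01, 0.02, 0.02, 0.01), 2), n_families = 30)
  expect_error(resample_G(bad, iters = 2, seed = 1), "positive semi-definite")
})

test_that("Wishart D draws are unbiased for D", {
  D <- g_matrix(3 * as_mat(toy_G3())); attr(D, "n_pops") <- 8
  draws <- resample_D(D, iters = 3000, seed = 6)
  arr <- simplify2array(draws)
  mean_mat <- apply(arr, 1:2, mean)
  se_mat <- apply(arr, 1:2, stats::sd) / sqrt(length(draws))
  expect_true(all(abs(mean_mat - as_mat(D)) <= 3.5 * se_mat + 1e-12))
})

test_that("slope SEs behave like Monte-Carlo sampling theory predicts", {
  case <- toy_case()
  # degenerate draw lists reproduce the point estimate: SE 0
  Gd <- replicate(120, as_mat(case$G), simplify = FALSE)
  Dd <- replicate(120, as_mat(case$D), simplify = FALSE)
  expect_equal(slope_se(case, "G_eigen", Gd, Dd, pairings = 50,
                        seed = 1)$se, 0)
  # SE decreases with the effective sample size of the G draws
  # (D draws held at the point estimate to isolate G sampling noise)
  se_small <- slope_se(case, "G_eigen",
                       resample_G(case$G, 300, seed = 3, n_families = 10),
                       Dd, pairings = 400, seed = 4)$se
  se_big <- slope_se(case, "G_eigen",
                     resample_G(case$G, 300, seed = 5, n_families = 200),
                     Dd, pairings = 400, seed = 6)$se
  expect_lt(se_big, se_small)
  D_draws <- resample_D(case$D, iters = 300, seed = 2)
  # Monte-Carlo convergence: doubling pairings moves the SE < 10%
  Gd2 <- resample_G(case$G, 400, seed = 7)
  s500 <- slope_se(case, "G_eigen", Gd2, D_draws, pairings = 500,
                   seed = 8)$se
  s1000 <- slope_se(case, "G_eigen", Gd2, D_draws, pairings = 1000,
                    seed = 9)$se
  expect_lt(abs(s1000 - s500) / s500, 0.1)
})

test_that("grand slopes reduce to case slopes and weighted means", {
  one <- data.frame(slope = 0.9, se = 0.1, species = "s1",
                    d_matrix_id = "d1", r2 = 0.8)
  g1 <- meta_slope(one)
  expect_equal(g1$slope, 0.9)
  expect_equal(g1$n_cases, 1L)
  four <- data.frame(slope = c(0.8, 1.0, 1.2, 1.0),
                     se = rep(0.2, 4),
                     species = c("s1", "s1", "s2", "s2"),
                     d_matrix_id = paste0("d", 1:4),
                     r2 = c(0.7, 0.8, 0.9, 0.6))
  g4 <- suppressWarnings(meta_slope(four))
  expect_equal(g4$slope, 1.0, tolerance = 1e-6)
  expect_equal(g4$median_r2, 0.75)
  # missing SEs fall back to equal weights with a warning
  four$se <- NA_real_
  expect_warning(meta_slope(four), "equal weights")
})
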