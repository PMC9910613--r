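test_that("simulated G-matrices are PSD with the requested mean scale", {
  G <- simulate_G(4, scale = 0.006, seed = 1)
  expect_equal(sum(diag(as_mat(G))) / 4, 0.006, tolerance = 1e-12)
  expect_silent(chol(as_mat(G)))
  expect_identical(as_mat(simulate_G(4, seed = 2)),
                   as_mat(simulate_G(4, seed = 2)))
  expect_false(identical(as_mat(simulate_G(4, seed = 2)),
                         as_mat(simulate_G(4, seed = 3))))
})

test_that("neutral population means have among-population covariance t/Ne G", {
  G <- toy_G3()
  sim <- simulate_population_means(G, n_pops = 4000, t_over_Ne = 1,
                                   seed = 4)
  D_hat <- stats::cov(sim$ln_means)
  # elementwise agreement within Monte-Carlo error (cov entries have
  # sd ~ sqrt((g_ii g_jj + g_ij^2)/n))
  Gm <- as_mat(G)
  tol <- 4 * sqrt((outer(diag(Gm), diag(Gm)) + Gm^2) / 4000)
  expect_true(all(abs(D_hat - Gm) < tol))
  expect_equal(as_mat(sim$true_D), Gm, ignore_attr = TRUE)
  # t/Ne = 0: all populations identical when sampling noise is off
  sim0 <- simulate_population_means(G, n_pops = 5, t_over_Ne = 0, seed = 5)
  expect_equal(max(apply(sim0$ln_means, 2, stats::sd)), 0)
  # finite individuals add sampling noise
  simn <- simulate_population_means(G, n_pops = 5, t_over_Ne = 0,
                                    n_individuals = 50, h2 = 0.3, seed = 5)
  expect_gt(max(apply(simn$ln_means, 2, stats::sd)), 0)
})

test_that("OU divergence shares G eigenvectors with powered eigenvalues", {
  G <- toy_G3()
  sim <- simulate_population_means(G, n_pops = 5, model = "ou", ou_s = 0.7,
                                   seed = 6)
  edG <- eigen_directions(G)
  edD <- eigen_directions(sim$true_D)
  expect_equal(abs(edD$vectors), abs(edG$vectors), tolerance = 1e-8)
  # log eigenvalues are affine in log G eigenvalues with slope s
  b <- stats::coef(lm(log(edD$values) ~ log(edG$values)))[2]
  expect_equal(unname(b), 0.7, tolerance = 1e-10)
  # trace preserved at t/Ne = 1
  expect_equal(sum(diag(as_mat(sim$true_D))), sum(diag(as_mat(G))),
               tolerance = 1e-12)
  # s = 1 reduces to neutral scaling
  sim1 <- simulate_population_means(G, n_pops = 5, model = "ou", ou_s = 1,
                                    t_over_Ne = 2, seed = 7)
  expect_equal(as_mat(sim1$true_D), 2 * as_mat(G), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("evolvability estimates are unbiased with the requested spread", {
  G <- toy_G3()
  est0 <- simulate_evolvability_estimates(G, 0, n_estimates = 2, seed = 8)
  expect_equal(est0$estimate, unname(rep(diag(as_mat(G)), each = 2)),
               tolerance = 1e-12)
  est <- simulate_evolvability_estimates(G, 0.4, n_estimates = 4000,
                                         seed = 9)
  by_trait <- split(est$estimate, est$trait)
  for (tr in names(by_trait)) {
    expect_equal(stats::sd(log(by_trait[[tr]])), 0.4, tolerance = 0.03)
    expect_equal(unname(mean(by_trait[[tr]])),
                 unname(diag(as_mat(G))[tr]), tolerance = 0.05)
  }
  expect_equal(attr(est, "true_V_me"), 0.16)
})

test_that("database generation is deterministic and internally consistent", {
  db <- shared_db()
  db2 <- simulate_database(sim_config(n_species = 6, studies_per_species = 2,
                                      seed = 101))
  expect_identical(db$pop_means, db2$pop_means)
  expect_identical(db$evolvability, db2$evolvability)
  db3 <- simulate_database(sim_config(n_species = 6, studies_per_species = 2,
                                      seed = 102))
  expect_false(identical(db$pop_means, db3$pop_means))

  expect_equal(nrow(db$studies), 12)
  expect_setequal(unique(db$pop_means$study_id), db$studies$study_id)
  # every study has the configured number of populations and traits
  for (i in seq_len(nrow(db$studies))) {
    sid <- db$studies$study_id[i]
    pm <- db$pop_means[db$pop_means$study_id == sid, ]
    expect_equal(length(unique(pm$population_id)), db$studies$n_pops[i])
    expect_setequal(unique(pm$trait), db$traits$trait)
    expect_true(all(pm$mean > 0))
  }
  # matrices carry matched trait sets and family counts
  m1 <- db$matrices[[db$studies$study_id[1]]]
  expect_identical(rownames(m1$G), db$traits$trait)
  expect_equal(attr(m1$G, "n_families"), 60)
  # ground truth records the generative slope and d/e
  expect_equal(db$ground_truth$true_slope, 1)
  expect_equal(db$ground_truth$t_over_Ne, 1)
})

test_that("database CSV round trip feeds the pipeline readers", {
  db <- shared_db()
  dir <- withr::local_tempdir()
  write_database(db, dir)
  db_r <- read_database(dir)
  expect_equal(db_r$pop_means$mean, db$pop_means$mean, tolerance = 1e-12)
  expect_equal(as_mat(db_r$matrices[[db$studies$study_id[1]]]$G),
               as_mat(db$matrices[[db$studies$study_id[1]]]$G),
               tolerance = 1e-12)
  expect_equal(attr(db_r$matrices[[db$studies$study_id[1]]]$G,
                    "n_families"), 60)
  # a read-back database supports the univariate pipeline end to end
  u <- suppressWarnings(run_univariate(db_r, moderators = character()))
  u0 <- suppressWarnings(run_univariate(db, moderators = character()))
  expect_equal(u$raw_slope, u0$raw_slope, tolerance = 1e-6)
})

test_that("category effects scale divergence of the labelled traits", {
  cf <- sim_config(n_species = 6, studies_per_species = 2,
                   category_effects = c(floral = 1, vegetative = 4),
                   seed = 55)
  db <- simulate_database(cf)
  td <- db$ground_truth$true_d
  ratio <- mean(td$true_d[td$trait_category == "vegetative"] /
                  td$true_e[td$trait_category == "vegetative"]) /
    mean(td$true_d[td$trait_category == "floral"] /
           td$true_e[td$trait_category == "floral"])
  expect_equal(ratio, 4, tolerance = 1e-10)
  expect_gt(db$ground_truth$category_median_dP$true_median_dP[2],
            db$ground_truth$category_median_dP$true_median_dP[1])
})
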