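#' Configuration for the synthetic database generator
#'
#' Bundles and validates the parameters of [simulate_database()]. Defaults
#' describe a database of realistic scale for this literature: 16 species
#' with 3 divergence studies each (48 studies), 5 traits per species, 5-12
#' populations per study, G-matrices from breeding designs of 60 families,
#' a mean evolvability of 0.5% (the typical magnitude of mean-scaled
#' additive variance in plants), population means from 100 measured
#' individuals each, neutral divergence with `t_over_Ne = 1` (so the
#' expected divergence/evolvability ratio is 1 along every direction), and
#' log-scale noise of SD 0.3 on individual evolvability estimates.
#'
#' @param n_species number of species.
#' @param studies_per_species divergence studies per species (all sharing
#'   the species' true G-matrix).
#' @param k_traits traits per species (>= 3 for multivariate use).
#' @param n_pops populations per divergence study (>= 3): a single count,
#'   or a `c(min, max)` range sampled uniformly per study.
#' @param n_families effective families behind each G estimate.
#' @param n_individuals_per_pop individuals measured per population
#'   (controls sampling noise of population means; `Inf` disables it).
#' @param mean_evolvability_scale target mean evolvability (trace(G)/k).
#' @param wishart_df degrees of freedom of the Wishart draw generating true
#'   G-matrices (>= k; lower values give more eccentric matrices).
#' @param divergence_model `"neutral"` (among-population covariance
#'   proportional to G) or `"ou"` (optimum tracking under an
#'   Ornstein-Uhlenbeck process: shared eigenvectors, eigenvalues raised to
#'   `ou_s`).
#' @param t_over_Ne divergence time over effective population size; under
#'   neutrality the true d/e ratio along every direction.
#' @param ou_s eigenvalue exponent of the OU stationary covariance
#'   (`0.5 <= s <= 1`; `s = 1` reduces to neutral scaling).
#' @param measurement_noise SD of the log-scale noise on individual
#'   evolvability estimates.
#' @param n_estimates repeated evolvability estimates per species-trait.
#' @param category_effects named multiplicative offsets of the divergence
#'   (d) scale per trait category, e.g. `c(floral = 1, vegetative = 3)`.
#' @param h2 heritability used to derive the phenotypic matrix `P = G/h2`.
#' @param exact_matrices if `TRUE`, the database exposes the true G and D
#'   matrices to the pipeline (bypassing estimation noise); otherwise
#'   estimated matrices are exposed.
#' @param seed integer seed for the whole database.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_species = 16, studies_per_species = 3,
                       k_traits = 5, n_pops = c(5, 12), n_families = 60,
                       n_individuals_per_pop = 100,
                       mean_evolvability_scale = 0.005,
                       wishart_df = 3 * k_traits,
                       divergence_model = c("neutral", "ou"),
                       t_over_Ne = 1, ou_s = 0.7,
                       measurement_noise = 0.3, n_estimates = 3,
                       category_effects = c(floral = 1, vegetative = 1),
                       h2 = 0.3, exact_matrices = FALSE, seed = 1) {
  divergence_model <- match.arg(divergence_model)
  stopifnot(n_species >= 1, studies_per_species >= 1, k_traits >= 3,
            all(n_pops >= 3), length(n_pops) %in% 1:2,
            n_families >= 2, mean_evolvability_scale > 0,
            wishart_df >= k_traits, t_over_Ne >= 0,
            ou_s >= 0.5, ou_s <= 1, measurement_noise >= 0,
            n_estimates >= 1, h2 > 0, h2 <= 1)
  if (is.null(names(category_effects)) ||
      !all(c("floral", "vegetative") %in% names(category_effects)))
    stop("'category_effects' must be named with floral and vegetative",
         call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a true G-matrix
#'
#' Draws a Wishart-distributed positive-definite matrix around a
#' compound-symmetric base correlation (correlation `rho`) and rescales it
#' so that `trace(G)/k` equals `scale`. Lower `df` yields more eccentric
#' matrices (greater spread of eigenvalues).
#'
#' @param k number of traits.
#' @param scale target mean evolvability (trace/k).
#' @param df Wishart degrees of freedom (>= k).
#' @param seed optional integer seed.
#' @param rho base correlation of the Wishart scale matrix.
#' @param n_families effective-family attribute attached to the result.
#' @param labels trait labels.
#' @return a [g_matrix()].
#' @export
simulate_G <- function(k, scale = 0.005, df = 3 * k, seed = NULL,
                       rho = 0.3, n_families = NA_integer_,
                       labels = paste0("t", seq_len(k))) {
  stopifnot(df >= k)
  base <- matrix(rho, k, k); diag(base) <- 1
  with_seed(seed, {
    w <- stats::rWishart(1, df = df, Sigma = base / df)[, , 1]
    w <- w * scale / (sum(diag(w)) / k)
    g_matrix(w, trait_labels = labels, n_families = n_families,
             sym_tol = 1e-8)
  })
}

# Among-population covariance of log means implied by the divergence model.
# category_scale multiplies the d scale per trait (entering as
# sqrt(c_i c_j) on covariances so the matrix stays PSD).
divergence_covariance <- function(G, model, t_over_Ne, ou_s,
                                  category_scale = NULL) {
  Gm <- as_plain_matrix(G)
  if (model == "ou") {
    e <- eigen(Gm, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    lam_ou <- lam^ou_s
    lam_ou <- lam_ou * sum(lam) / sum(lam_ou)  # preserve trace
    Gm <- e$vectors %*% diag(lam_ou, nrow(Gm)) %*% t(e$vectors)
  }
  cov <- t_over_Ne * Gm
  if (!is.null(category_scale)) {
    s <- sqrt(category_scale)
    cov <- cov * tcrossprod(s)
  }
  dimnames(cov) <- dimnames(Gm) %||% dimnames(as_plain_matrix(G))
  (cov + t(cov)) / 2
}

#' Simulate population trait means under neutral or OU divergence
#'
#' Log population means are drawn from a multivariate normal centered on the
#' log ancestral means with among-population covariance `t_over_Ne * G`
#' (neutral drift: divergence proportional to standing variation along every
#' direction, so the true d/e ratio is `t_over_Ne`) or, under `"ou"`, a
#' stationary optimum-tracking covariance sharing the eigenvectors of G
#' with eigenvalues raised to the power `ou_s` (trace preserved), which
#' yields a true log-log evolvability-divergence slope of `ou_s` along the
#' G eigenvectors. Finite `n_individuals` adds per-population sampling noise
#' of log-scale variance `diag(G)/h2/n_individuals` (the mean-scaled
#' phenotypic variance of a sample mean).
#'
#' @param G true [g_matrix()].
#' @param n_pops number of populations.
#' @param model `"neutral"` or `"ou"`.
#' @param t_over_Ne divergence scale (see [sim_config()]).
#' @param ou_s OU eigenvalue exponent.
#' @param base_means ancestral trait means; default drawn log-normally.
#' @param n_individuals individuals per population mean (`Inf`: none).
#' @param h2 heritability linking G to the phenotypic variance.
#' @param category_scale optional per-trait multiplicative d offsets.
#' @param seed optional integer seed.
#' @return list with `means_table` (long data frame: `population_id`,
#'   `trait`, `mean`), `ln_means` (n_pops x k matrix), and `true_D`
#'   (the generative among-population covariance as a [g_matrix()]).
#' @export
simulate_population_means <- function(G, n_pops, model = "neutral",
                                      t_over_Ne = 1, ou_s = 0.7,
                                      base_means = NULL,
                                      n_individuals = Inf, h2 = 0.3,
                                      category_scale = NULL, seed = NULL) {
  k <- nrow(G)
  labs <- trait_labels(G)
  cov <- divergence_covariance(G, model, t_over_Ne, ou_s, category_scale)
  with_seed(seed, {
    if (is.null(base_means)) base_means <- exp(stats::rnorm(k, 2, 0.5))
    mu <- log(base_means)
    ln <- if (all(cov == 0)) {
      matrix(mu, n_pops, k, byrow = TRUE)
    } else {
      MASS::mvrnorm(n_pops, mu = mu, Sigma = cov)
    }
    if (is.finite(n_individuals)) {
      sv <- diag(as_plain_matrix(G)) / h2 / n_individuals
      ln <- ln + matrix(stats::rnorm(n_pops * k, 0, rep(sqrt(sv),
                                                        each = n_pops)),
                        n_pops, k)
    }
    dimnames(ln) <- list(sprintf("pop%02d", seq_len(n_pops)), labs)
    means_table <- data.frame(
      population_id = rep(rownames(ln), k),
      trait = rep(labs, each = n_pops),
      mean = exp(as.vector(ln)))
    list(means_table = means_table, ln_means = ln,
         true_D = g_matrix(cov, trait_labels = labs, sym_tol = 1e-8))
  })
}

#' Simulate repeated noisy evolvability estimates
#'
#' Per trait, draws `n_estimates` mean-one log-normal perturbations of the
#' true diagonal evolvability: `estimate = e_true * exp(z - sd^2/2)` with
#' `z ~ N(0, noise_sd^2)`, so estimates are unbiased on the variance scale
#' while their log-scale spread (`noise_sd^2` per estimate) generates the
#' attenuation the downstream correction must undo.
#'
#' @param G true [g_matrix()].
#' @param noise_sd log-scale SD of the estimation noise.
#' @param n_estimates repeated estimates per trait.
#' @param seed optional integer seed.
#' @return data frame with columns `trait`, `rep`, `estimate`, plus
#'   attribute `true_V_me = noise_sd^2` (log-scale error variance per
#'   single estimate).
#' @export
simulate_evolvability_estimates <- function(G, noise_sd, n_estimates = 3,
                                            seed = NULL) {
  stopifnot(noise_sd >= 0)
  labs <- trait_labels(G)
  e_true <- diag(as_plain_matrix(G))
  with_seed(seed, {
    z <- stats::rnorm(length(labs) * n_estimates, 0, noise_sd)
    out <- data.frame(
      trait = rep(labs, each = n_estimates),
      rep = rep(seq_len(n_estimates), length(labs)),
      estimate = rep(e_true, each = n_estimates) *
        exp(z - noise_sd^2 / 2))
    attr(out, "true_V_me") <- noise_sd^2
    out
  })
}

#' Simulate a complete synthetic database
#'
#' Wires the generators together into a database with the hierarchical
#' structure of the empirical literature — species carrying true G-matrices,
#' divergence studies of several populations each, repeated noisy
#' evolvability estimates per species-trait, trait-category labels,
#' mating-system and study-environment metadata, and geographic coordinates
#' — together with the ground truth needed for recovery tests.
#'
#' Unless `exact_matrices` is set, the matrices exposed to the pipeline are
#' estimated: per-study G as the sample covariance of `n_families`
#' mean-one multivariate-normal draws from the true G, and P likewise from
#' `P = G/h2` using the total number of individuals.
#'
#' @param config a [sim_config()].
#' @return object of class `syn_database`: list with `evolvability`,
#'   `pop_means`, `studies`, `traits`, `matrices` (per-study list with
#'   `G`, `P`, `G_true`, `true_D`), `ground_truth`, and `config`.
#' @export
simulate_database <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  k <- cf$k_traits
  n_cat_floral <- ceiling(k / 2)
  trait_cat <- c(rep("floral", n_cat_floral),
                 rep("vegetative", k - n_cat_floral))
  traits <- data.frame(trait = paste0("t", seq_len(k)),
                       trait_category = trait_cat)
  cat_scale <- unname(cf$category_effects[trait_cat])

  seeds <- child_seeds(cf$seed, 4)
  sp_seeds <- child_seeds(seeds[[1]], cf$n_species)

  evol <- list(); popm <- list(); studies <- list(); mats <- list()
  true_d <- list()
  with_seed(seeds[[2]], {
    mating <- sample(c("selfing", "mixed", "outcrossing"), cf$n_species,
                     replace = TRUE, prob = c(0.25, 0.45, 0.30))
  })

  for (s in seq_len(cf$n_species)) {
    sp <- sprintf("species%03d", s)
    ss <- child_seeds(sp_seeds[[s]], 3 + cf$studies_per_species)
    G_true <- simulate_G(k, scale = cf$mean_evolvability_scale,
                         df = cf$wishart_df, seed = ss[[1]],
                         n_families = cf$n_families)
    est <- simulate_evolvability_estimates(G_true, cf$measurement_noise,
                                           cf$n_estimates, seed = ss[[2]])
    est$species <- sp
    evol[[sp]] <- merge(est, traits, by = "trait")

    P_true <- g_matrix(as_plain_matrix(G_true) / cf$h2,
                       trait_labels = trait_labels(G_true), sym_tol = 1e-8)

    for (j in seq_len(cf$studies_per_species)) {
      sid <- sprintf("%s_study%d", sp, j)
      st_seeds <- child_seeds(ss[[3 + j]], 5)
      np <- if (length(cf$n_pops) == 1) cf$n_pops else
        with_seed(st_seeds[[5]],
                  sample(seq(cf$n_pops[1], cf$n_pops[2]), 1))
      sim <- simulate_population_means(
        G_true, np, model = cf$divergence_model,
        t_over_Ne = cf$t_over_Ne, ou_s = cf$ou_s,
        n_individuals = cf$n_individuals_per_pop, h2 = cf$h2,
        category_scale = cat_scale, seed = st_seeds[[1]])

      coords <- with_seed(st_seeds[[2]], {
        center <- c(stats::runif(1, -40, 60), stats::runif(1, -120, 120))
        span <- stats::runif(1, 0.2, 5)
        data.frame(
          population_id = rownames(sim$ln_means),
          lat = center[1] + stats::runif(np, -span / 2, span / 2),
          lon = center[2] + stats::runif(np, -span / 2, span / 2))
      })

      mt <- merge(sim$means_table, coords, by = "population_id")
      mt <- mt[order(mt$population_id, match(mt$trait, traits$trait)), ]
      mt$species <- sp; mt$study_id <- sid
      env <- with_seed(st_seeds[[3]],
                       sample(c("greenhouse", "common_garden", "field"), 1,
                              prob = c(0.60, 0.15, 0.25)))
      mt$environment <- env
      popm[[sid]] <- mt

      studies[[sid]] <- data.frame(
        study_id = sid, species = sp, environment = env,
        n_pops = np, n_families = cf$n_families,
        max_dist_km = study_max_distance(coords$lat, coords$lon),
        mating_system = mating[s])

      mest <- with_seed(st_seeds[[4]], {
        G_est <- stats::cov(MASS::mvrnorm(cf$n_families, mu = rep(1, k),
                                          Sigma = as_plain_matrix(G_true)))
        n_ind <- np * min(cf$n_individuals_per_pop, 1000)
        P_est <- stats::cov(MASS::mvrnorm(max(n_ind, k + 2),
                                          mu = rep(1, k),
                                          Sigma = as_plain_matrix(P_true)))
        list(G_est = G_est, P_est = P_est)
      })
      to_g <- function(m) g_matrix(m, trait_labels = traits$trait,
                                   n_families = cf$n_families,
                                   species = sp, study_id = sid,
                                   sym_tol = 1e-8)
      mats[[sid]] <- list(
        G = if (cf$exact_matrices) G_true else to_g(mest$G_est),
        P = if (cf$exact_matrices) P_true else to_g(mest$P_est),
        G_true = G_true, P_true = P_true, true_D = sim$true_D)

      true_d[[sid]] <- data.frame(
        species = sp, study_id = sid, trait = traits$trait,
        trait_category = trait_cat,
        true_d = diag(as_plain_matrix(sim$true_D)),
        true_e = diag(as_plain_matrix(G_true)))
    }
  }

  evolvability <- do.call(rbind, c(evol, make.row.names = FALSE))
  pop_means <- do.call(rbind, c(popm, make.row.names = FALSE))
  pop_means <- pop_means[, c("species", "study_id", "population_id",
                             "trait", "mean", "environment", "lat", "lon")]
  studies <- do.call(rbind, c(studies, make.row.names = FALSE))
  true_d <- do.call(rbind, c(true_d, make.row.names = FALSE))

  cat_med <- stats::aggregate(
    list(true_median_dP = proportional_divergence(true_d$true_d)),
    by = list(trait_category = true_d$trait_category), FUN = stats::median)

  structure(list(
    evolvability = evolvability, pop_means = pop_means, studies = studies,
    traits = traits, matrices = mats,
    ground_truth = list(
      true_slope = if (cf$divergence_model == "neutral") 1 else cf$ou_s,
      t_over_Ne = cf$t_over_Ne,
      true_V_me = cf$measurement_noise^2,
      category_effects = cf$category_effects,
      true_d = true_d, category_median_dP = cat_med),
    config = cf), class = "syn_database")
}

#' @export
print.syn_database <- function(x, ...) {
  np <- paste(unique(range(x$config$n_pops)), collapse = "-")
  cat(sprintf(paste0(
    "Synthetic database: %d species, %d studies, %d traits/species, ",
    "%s populations/study\n  model %s, t/Ne = %g, noise SD = %g, seed %s\n"),
    x$config$n_species, nrow(x$studies), x$config$k_traits,
    np, x$config$divergence_model, x$config$t_over_Ne,
    x$config$measurement_noise, x$config$seed))
  invisible(x)
}

#' Write / read a synthetic database as plain CSV files
#'
#' `write_database()` serializes the pipeline-facing tables
#' (`evolvability.csv`, `population_means.csv`, `studies.csv`,
#' `traits.csv`), the per-study G- and P-matrices as square labeled CSVs
#' under `matrices/`, and the scalar ground truth (`ground_truth.csv`).
#' `read_database()` reconstructs a database (without the unexposed true
#' matrices) that every pipeline function accepts.
#'
#' @param db a `syn_database`.
#' @param dir target directory (created if needed).
#' @return the directory (write) or a `syn_database`-compatible list (read).
#' @export
write_database <- function(db, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(db$evolvability, file.path(dir, "evolvability.csv"),
                   row.names = FALSE)
  utils::write.csv(db$pop_means, file.path(dir, "population_means.csv"),
                   row.names = FALSE)
  utils::write.csv(db$studies, file.path(dir, "studies.csv"),
                   row.names = FALSE)
  utils::write.csv(db$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  for (sid in names(db$matrices)) {
    write_matrix_csv(db$matrices[[sid]]$G,
                     file.path(dir, "matrices", paste0(sid, "_G.csv")))
    if (!is.null(db$matrices[[sid]]$P))
      write_matrix_csv(db$matrices[[sid]]$P,
                       file.path(dir, "matrices", paste0(sid, "_P.csv")))
  }
  gt <- db$ground_truth
  scal <- data.frame(key = c("true_slope", "t_over_Ne", "true_V_me"),
                     value = c(gt$true_slope, gt$t_over_Ne, gt$true_V_me))
  utils::write.csv(scal, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_database
#' @export
read_database <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  studies <- rd("studies.csv")
  mats <- list()
  for (i in seq_len(nrow(studies))) {
    sid <- studies$study_id[i]
    nf <- if ("n_families" %in% names(studies))
      studies$n_families[i] else NA_integer_
    gp <- file.path(dir, "matrices", paste0(sid, "_G.csv"))
    pp <- file.path(dir, "matrices", paste0(sid, "_P.csv"))
    mats[[sid]] <- list(
      G = if (file.exists(gp)) read_matrix_csv(gp, n_families = nf)
      else NULL,
      P = if (file.exists(pp)) read_matrix_csv(pp) else NULL)
  }
  gt <- rd("ground_truth.csv")
  structure(list(
    evolvability = rd("evolvability.csv"),
    pop_means = rd("population_means.csv"),
    studies = studies, traits = rd("traits.csv"), matrices = mats,
    ground_truth = as.list(stats::setNames(gt$value, gt$key)),
    config = NULL), class = "syn_database")
}
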