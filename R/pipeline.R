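#' Maximum great-circle distance among populations
#'
#' @param lat,lon coordinates in degrees.
#' @return maximum pairwise haversine distance in km (0 for a single point,
#'   `NA` when coordinates are missing).
#' @export
study_max_distance <- function(lat, lon) {
  ok <- is.finite(lat) & is.finite(lon)
  if (sum(ok) < 2) return(NA_real_)
  max(geosphere::distm(cbind(lon[ok], lat[ok]),
                       fun = geosphere::distHaversine)) / 1000
}

# Per (study, trait) divergence records joined with study/trait metadata.
divergence_records <- function(db) {
  pm <- db$pop_means
  keys <- unique(pm[, c("species", "study_id", "trait")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- pm$study_id == keys$study_id[i] & pm$trait == keys$trait[i]
    means <- stats::setNames(pm$mean[sel], pm$population_id[sel])
    d <- among_population_variance(means)
    data.frame(species = keys$species[i], study_id = keys$study_id[i],
               trait = keys$trait[i], d = d, n_pop = length(means),
               d_P = proportional_divergence(d))
  })
  recs <- do.call(rbind, c(rows, make.row.names = FALSE))
  recs <- merge(recs, db$traits, by = "trait")
  merge(recs, db$studies[, c("study_id", "environment", "mating_system",
                             "max_dist_km")],
        by = "study_id")
}

#' Patterns of population divergence
#'
#' Per-group medians of the proportional divergence factor `d_P` with
#' bootstrap SEs, grouped by trait category, mating system, and study
#' environment — the descriptive entry point of the analysis.
#'
#' @param db a database ([simulate_database()] output or compatible list).
#' @param by grouping columns to summarize over.
#' @param bootstrap_reps,seed bootstrap settings for the SE of the medians.
#' @return list with `records` (per study-trait `d`, `d_P`, labels) and
#'   `summaries` (named list of per-group median tables).
#' @export
run_patterns <- function(db, by = c("trait_category", "mating_system",
                                    "environment"),
                         bootstrap_reps = 2000, seed = NULL) {
  recs <- divergence_records(db)
  seeds <- child_seeds(seed, length(by))
  summaries <- stats::setNames(lapply(seq_along(by), function(i) {
    median_divergence_summary(recs$d_P, recs[[by[i]]],
                              bootstrap_reps = bootstrap_reps,
                              seed = seeds[[i]])
  }), by)
  list(records = recs, summaries = summaries)
}

# Assemble the meta-regression dataset: divergence records paired with the
# mean evolvability estimate per unique species-trait combination, weights
# from the log-scale measurement-error variance of d, centered covariates,
# and the quantities needed for the attenuation correction.
build_meta_dataset <- function(db, distance_policy = c("drop", "median"),
                               vme_method = c("mean_error", "within")) {
  distance_policy <- match.arg(distance_policy)
  vme_method <- match.arg(vme_method)
  recs <- divergence_records(db)

  ev <- db$evolvability
  agg <- do.call(rbind, lapply(
    split(ev, list(ev$species, ev$trait), drop = TRUE), function(g) {
      data.frame(species = g$species[1], trait = g$trait[1],
                 e_mean = mean(g$estimate),
                 m = nrow(g),
                 within_var = if (nrow(g) > 1) stats::var(log(g$estimate))
                 else NA_real_)
    }))
  ds <- merge(recs, agg, by = c("species", "trait"))

  n0 <- nrow(ds)
  ds <- ds[ds$d > 0 & ds$e_mean > 0, , drop = FALSE]
  n_dropped_zero <- n0 - nrow(ds)

  if (distance_policy == "median") {
    med <- stats::median(ds$max_dist_km[ds$max_dist_km > 0], na.rm = TRUE)
    ds$max_dist_km[!is.finite(ds$max_dist_km) | ds$max_dist_km <= 0] <- med
  }
  n1 <- nrow(ds)
  ds <- ds[is.finite(ds$max_dist_km) & ds$max_dist_km > 0, , drop = FALSE]
  n_dropped_dist <- n1 - nrow(ds)

  ds$log_d <- log(ds$d)
  ds$log_e <- log(ds$e_mean)
  ds$log_npop <- log(ds$n_pop)
  ds$log_dist <- log(ds$max_dist_km)
  # centered covariates: the intercept then refers to expected log d at the
  # mean covariate values
  for (v in c("log_e", "log_npop", "log_dist"))
    ds[[paste0(v, "_c")]] <- ds[[v]] - mean(ds[[v]])
  ds$weight <- 1 / measurement_error_variance(ds$d, ds$n_pop,
                                              log_scale = TRUE)

  V <- stats::var(ds$log_e)
  err_var <- ds$within_var / if (vme_method == "mean_error") ds$m else 1
  V_me <- mean(err_var, na.rm = TRUE)
  if (!is.finite(V_me)) V_me <- 0

  structure(ds, V = V, V_me = V_me, vme_method = vme_method,
            n_dropped_zero = n_dropped_zero,
            n_dropped_dist = n_dropped_dist)
}

#' Univariate evolvability-divergence meta-regression
#'
#' Fits the weighted random-slope meta-regression of log divergence on log
#' evolvability: fixed effects for log evolvability, log number of
#' populations, and log maximum geographic distance (all centered), random
#' intercepts for species and divergence study, a random slope for
#' evolvability per divergence study, and inverse measurement-error-variance
#' weights (`(n_pop + 2)/2`, the log-scale precision of each `d`). The
#' evolvability slope is then corrected for attenuation from estimation
#' error in the predictor, and moderator models (trait category, mating
#' system, environment interacting with evolvability) are compared against
#' the baseline by AIC (ML fits throughout).
#'
#' @param db a database.
#' @param moderators moderator columns to test (each needs >= 2 levels).
#' @param distance_policy how to treat studies without a usable geographic
#'   distance: drop their rows, or impute the median distance.
#' @param vme_method attenuation error variance: `"mean_error"` (error
#'   variance of the mean predictor, within-variance/m) or `"within"` (raw
#'   within species-trait variance of repeated log estimates).
#' @return object of class `univariate_fit` with elements `dataset`,
#'   `baseline` (a [meta_lmm()]), `raw_slope`, `raw_se`, `corrected`
#'   (from [attenuation_correct()]), `ci_corrected` (95% Wald), `r2`,
#'   `moderators` (per-moderator fits and delta-AIC table).
#' @export
run_univariate <- function(db, moderators = c("trait_category",
                                              "mating_system",
                                              "environment"),
                           distance_policy = "drop",
                           vme_method = "mean_error") {
  ds <- build_meta_dataset(db, distance_policy, vme_method)
  baseline <- meta_lmm(log_d ~ log_e_c + log_npop_c + log_dist_c,
                       data = ds, weights = "weight",
                       random_intercepts = c("species", "study_id"),
                       random_slope = c("log_e_c", "study_id"),
                       method = "ML")
  fe <- baseline$fixed_effects
  raw_slope <- fe$estimate[fe$term == "log_e_c"]
  raw_se <- fe$se[fe$term == "log_e_c"]
  corr <- attenuation_correct(raw_slope, attr(ds, "V_me"), attr(ds, "V"),
                              se = raw_se)
  ci <- corr$corrected + c(-1, 1) * 1.96 * corr$se_corrected

  mod_out <- list(); aic_tab <- list()
  for (m in moderators) {
    if (length(unique(ds[[m]])) < 2) next
    f <- stats::as.formula(paste(
      "log_d ~ log_e_c *", m, "+ log_npop_c + log_dist_c"))
    fit_m <- tryCatch(suppressWarnings(
      meta_lmm(f, data = ds, weights = "weight",
               random_intercepts = c("species", "study_id"),
               random_slope = c("log_e_c", "study_id"), method = "ML")),
      error = function(e) NULL)
    if (is.null(fit_m)) next
    cmp <- compare_aic(baseline, fit_m)
    mod_out[[m]] <- fit_m
    aic_tab[[m]] <- data.frame(moderator = m, delta_aic = cmp$delta_aic,
                               support = cmp$support)
  }
  structure(list(
    dataset = ds, baseline = baseline,
    raw_slope = raw_slope, raw_se = raw_se,
    corrected = corr, ci_corrected = ci,
    r2 = c(r2_marginal = baseline$r2_marginal,
           r2_conditional = baseline$r2_conditional),
    random_slope_sd = baseline$slope_sd,
    moderators = mod_out,
    delta_aic = if (length(aic_tab))
      do.call(rbind, c(aic_tab, make.row.names = FALSE)) else NULL),
    class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("Univariate evolvability-divergence meta-regression\n")
  cat(sprintf("  raw slope:       %.3f +/- %.3f\n", x$raw_slope, x$raw_se))
  cat(sprintf("  corrected slope: %.3f +/- %.3f (reliability %.3f)\n",
              x$corrected$corrected, x$corrected$se_corrected,
              x$corrected$reliability))
  cat(sprintf("  95%% CI (corrected): [%.3f, %.3f]\n",
              x$ci_corrected[1], x$ci_corrected[2]))
  cat(sprintf("  random-slope SD: %.3f | r2_M %.3f | r2_C %.3f | n = %d\n",
              x$random_slope_sd, x$r2["r2_marginal"],
              x$r2["r2_conditional"], x$baseline$n_obs))
  if (!is.null(x$delta_aic)) {
    cat("  moderator comparisons (AIC_complex - AIC_baseline):\n")
    print(x$delta_aic, row.names = FALSE)
  }
  invisible(x)
}

# Build the case registry from a database: one case per study with >= 3
# traits, pairing the study G with a D estimated from its population means
# (or the generative D when the database exposes exact matrices).
build_cases <- function(db, min_traits = 3) {
  exact <- isTRUE(db$config$exact_matrices)
  cases <- list()
  for (i in seq_len(nrow(db$studies))) {
    sid <- db$studies$study_id[i]
    mat <- db$matrices[[sid]]
    if (is.null(mat$G) || nrow(mat$G) < min_traits) next
    D <- if (exact && !is.null(mat$true_D)) {
      Dx <- mat$true_D
      attr(Dx, "n_pops") <- db$studies$n_pops[i]
      Dx
    } else {
      pm <- db$pop_means[db$pop_means$study_id == sid, , drop = FALSE]
      estimate_D_matrix(pm[, c("population_id", "trait", "mean")],
                        trait_subset = trait_labels(mat$G))
    }
    cases[[sid]] <- case_study(
      case_id = sid, G = mat$G, D = D, P = mat$P,
      species = db$studies$species[i], d_matrix_id = sid,
      n_pops = db$studies$n_pops[i])
  }
  cases
}

#' Multivariate evolvability-divergence analysis across cases
#'
#' For every paired G/D case in the database, regresses log divergence on
#' log evolvability over each requested direction set (original traits and
#' G-, D-, P-eigenvectors), attaches Monte-Carlo slope SEs from randomly
#' paired draws of the G and D sampling distributions, and summarizes each
#' direction set by the error-weighed grand slope (mixed model with species
#' and D-matrix random intercepts) and the median within-case r2.
#'
#' @param db a database.
#' @param which_sets direction sets to analyze.
#' @param conditional substitute conditional evolvability for evolvability.
#' @param iters Monte-Carlo draws per matrix sampling distribution.
#' @param pairings random (G, D) draw pairs per slope SE.
#' @param seed integer seed for all Monte Carlo.
#' @param min_traits minimum trait count for a case.
#' @return object of class `multivariate_fit`: list with `case_results`
#'   (data frame: case, set, slope, se, r2, ...) and `grand` (data frame of
#'   error-weighed slopes per direction set).
#' @export
run_multivariate <- function(db, which_sets = c("original", "G_eigen",
                                                "D_eigen", "P_eigen"),
                             conditional = FALSE, iters = 300,
                             pairings = 300, seed = NULL, min_traits = 3) {
  cases <- build_cases(db, min_traits)
  if (!length(cases)) stop("no usable cases in database", call. = FALSE)
  seeds <- child_seeds(seed, length(cases))
  rows <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    cs <- child_seeds(seeds[[ci]], 2 + length(which_sets))
    G_draws <- resample_G(case$G, iters = iters, seed = cs[[1]])
    D_draws <- resample_D(case$D, n_pops = case$n_pops, iters = iters,
                          seed = cs[[2]])
    for (si in seq_along(which_sets)) {
      set <- which_sets[si]
      if (set == "P_eigen" && is.null(case$P)) next
      reg <- tryCatch(suppressWarnings(
        case_regression(case, set, conditional = conditional)),
        error = function(e) NULL)
      if (is.null(reg)) next
      se <- tryCatch(suppressWarnings(
        slope_se(case, set, G_draws, D_draws, pairings = pairings,
                 seed = cs[[2 + si]], conditional = conditional)$se),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$case_id, species = case$species,
        d_matrix_id = case$d_matrix_id, set = set,
        slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
        se = se, n_directions = reg$n_directions,
        n_dropped = reg$n_dropped)
    }
  }
  case_results <- do.call(rbind, c(rows, make.row.names = FALSE))
  grand <- do.call(rbind, lapply(split(case_results, case_results$set),
                                 function(g) {
    gs <- meta_slope(g)
    data.frame(set = g$set[1], slope = gs$slope, se = gs$se,
               median_r2 = gs$median_r2, n_cases = gs$n_cases)
  }))
  rownames(grand) <- NULL
  structure(list(case_results = case_results, grand = grand,
                 conditional = conditional),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat("Multivariate evolvability-divergence analysis",
      if (x$conditional) "(conditional evolvability)" else "", "\n")
  cat("Error-weighed grand slopes per direction set:\n")
  g <- x$grand
  g$slope <- round(g$slope, 3); g$se <- round(g$se, 3)
  g$median_r2 <- round(g$median_r2, 3)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Evolvability along observed divergence vectors, database-wide
#'
#' For each study, takes the first population (alphabetically) as the focal
#' population carrying the G-matrix, computes the divergence vector to
#' every other population, and evaluates the evolvability and conditional
#' evolvability along it. Summaries report the proportions of populations
#' that diverged along directions of above-average (conditional)
#' evolvability and the error-weighed mean log ratios, plus per-study
#' divergence-vs-evolvability rank correlations.
#'
#' @param db a database.
#' @param mc_samples Monte-Carlo directions for the mean conditional
#'   evolvability of each G.
#' @param iters resampling draws for the sampling variances of log ratios
#'   (0 disables; equal weights are then used).
#' @param seed integer seed.
#' @return object of class `divvec_fit`: list with `records` (one row per
#'   focal-target pair), `summary` (from [above_average_summary()]), and
#'   `by_study` (from [divergence_vs_evolvability_table()]).
#' @export
run_divergence_vectors <- function(db, mc_samples = 10000, iters = 200,
                                   seed = NULL) {
  seeds <- child_seeds(seed, nrow(db$studies))
  rows <- list()
  for (i in seq_len(nrow(db$studies))) {
    sid <- db$studies$study_id[i]
    G <- db$matrices[[sid]]$G
    if (is.null(G)) next
    pm <- db$pop_means[db$pop_means$study_id == sid, , drop = FALSE]
    pops <- sort(unique(pm$population_id))
    if (length(pops) < 2) next
    cs <- child_seeds(seeds[[i]], 2)
    smry <- matrix_summary(G, mc_samples = mc_samples, seed = cs[[1]])
    g_draws <- if (iters > 0)
      resample_G(G, iters = iters, seed = cs[[2]]) else NULL
    get_means <- function(p) {
      sel <- pm$population_id == p
      stats::setNames(pm$mean[sel], pm$trait[sel])
    }
    focal <- get_means(pops[1])
    for (p in pops[-1]) {
      rec <- vector_evolvabilities(G, focal, get_means(p),
                                   summary = smry, g_draws = g_draws)
      if (isTRUE(rec$skipped)) next
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = sid, g_matrix_id = sid,
        focal_population = pops[1], population_id = p,
        d_mag = rec$d_mag, e_along = rec$e_along, c_along = rec$c_along,
        e_mean = rec$e_mean, c_mean = rec$c_mean,
        e_ratio = rec$e_ratio, c_ratio = rec$c_ratio,
        var_log_e_ratio = rec$var_log_e_ratio,
        var_log_c_ratio = rec$var_log_c_ratio)
    }
  }
  if (!length(rows)) stop("no divergence-vector records", call. = FALSE)
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(list(records = records,
                 summary = above_average_summary(records),
                 by_study = divergence_vs_evolvability_table(records)),
            class = "divvec_fit")
}

#' @export
print.divvec_fit <- function(x, ...) {
  s <- x$summary
  cat("Evolvability along observed divergence vectors\n")
  cat(sprintf("  records: %d\n", s$n))
  cat(sprintf("  diverged along above-average e: %.1f%%\n",
              100 * s$prop_above_e))
  if (!is.null(s$prop_above_c))
    cat(sprintf("  diverged along above-average c: %.1f%%\n",
                100 * s$prop_above_c))
  cat(sprintf("  mean e ratio: %.2f (log %.3f +/- %.3f)\n",
              s$ratio_e, s$mean_log_e_ratio, s$se_log_e_ratio))
  if (!is.null(s$ratio_c))
    cat(sprintf("  mean c ratio: %.2f (log %.3f +/- %.3f)\n",
                s$ratio_c, s$mean_log_c_ratio, s$se_log_c_ratio))
  invisible(x)
}

#' Divergence/evolvability ratio across paired trait estimates
#'
#' Pairs each per-trait divergence estimate with the mean evolvability
#' estimate for the species-trait combination and summarizes the d/e
#' ratios. Under neutral evolution d/e estimates t/Ne (divergence time over
#' effective population size) for every trait, so a mean ratio near 1
#' implies divergence times comparable to effective population sizes.
#'
#' @param db a database.
#' @return list with `ratios` (per study-trait data frame), `mean`,
#'   `median`, and `n_dropped` (rows with zero evolvability).
#' @export
compute_de_ratio <- function(db) {
  recs <- divergence_records(db)
  ev <- db$evolvability
  agg <- stats::aggregate(list(e_mean = ev$estimate),
                          by = list(species = ev$species, trait = ev$trait),
                          FUN = mean)
  ds <- merge(recs, agg, by = c("species", "trait"))
  n0 <- nrow(ds)
  ds <- ds[ds$e_mean > 0, , drop = FALSE]
  ds$ratio <- ds$d / ds$e_mean
  list(ratios = ds[, c("species", "study_id", "trait", "d", "e_mean",
                       "ratio")],
       mean = mean(ds$ratio), median = stats::median(ds$ratio),
       n_dropped = n0 - nrow(ds))
}
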