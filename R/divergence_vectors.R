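#' Evolvability along an observed divergence vector
#'
#' Computes the divergence vector from a focal population (where the
#' G-matrix was estimated) to a target population, and the evolvability
#' `e(u) = u'Gu` and conditional evolvability `c(u) = (u'G^{-1}u)^{-1}`
#' along its unit direction `u`. Ratios against the matrix mean
#' evolvabilities (`e_ratio = e(u)/e_mean`, `c_ratio = c(u)/c_mean`) say
#' whether the population diverged along a direction of above-average
#' evolvability. When resampled G draws are supplied, sampling variances of
#' the log ratios are estimated as the variance of the log ratio across
#' draws (directions held at the observed divergence vector).
#'
#' @param G focal-population [g_matrix()].
#' @param focal_means,target_means strictly positive named trait means.
#' @param summary optional precomputed [matrix_summary()] of `G`.
#' @param g_draws optional list of matrices from [resample_G()].
#' @param mc_samples,seed passed to [matrix_summary()] when `summary` is
#'   not supplied.
#' @return list record with fields `focal_population` (unset; caller fills
#'   ids), `d_mag`, `e_along`, `c_along`, `e_ratio`, `c_ratio`,
#'   `var_log_e_ratio`, `var_log_c_ratio`, `skipped` (TRUE with a `reason`
#'   for zero-magnitude divergence).
#' @export
vector_evolvabilities <- function(G, focal_means, target_means,
                                  summary = NULL, g_draws = NULL,
                                  mc_samples = 10000, seed = NULL) {
  dv <- divergence_vector(focal_means, target_means)
  if (dv$magnitude == 0)
    return(list(skipped = TRUE, reason = "zero-magnitude divergence vector",
                d_mag = 0))
  u <- dv$unit_direction
  s <- summary %||% matrix_summary(G, mc_samples = mc_samples, seed = seed)
  e_along <- evolvability_along(G, u)
  c_along <- conditional_evolvability_along(G, u)
  rec <- list(skipped = FALSE,
              d_mag = dv$magnitude, delta = dv$delta,
              e_along = e_along, c_along = c_along,
              e_mean = s$e_mean, c_mean = s$c_mean,
              e_ratio = e_along / s$e_mean,
              c_ratio = c_along / s$c_mean,
              var_log_e_ratio = NA_real_, var_log_c_ratio = NA_real_)
  if (!is.null(g_draws)) {
    labs <- trait_labels(G)
    uu <- align_direction(dv$unit_direction, G)
    lr_e <- rep(NA_real_, length(g_draws))
    lr_c <- rep(NA_real_, length(g_draws))
    k <- nrow(G)
    for (i in seq_along(g_draws)) {
      Gd <- g_draws[[i]]
      e_d <- drop(crossprod(uu, Gd %*% uu))
      em_d <- sum(diag(Gd)) / k
      if (e_d > 0 && em_d > 0) lr_e[i] <- log(e_d / em_d)
      cd <- tryCatch(1 / drop(crossprod(uu, solve(Gd, uu))),
                     error = function(e) NA_real_)
      # conditional ratio draws use the draw's own mean conditional
      # evolvability via the harmonic-mean identity is expensive; the
      # point-estimate c_mean is used as the (common) denominator, which
      # cancels in the variance of the log ratio.
      if (is.finite(cd) && cd > 0) lr_c[i] <- log(cd / s$c_mean)
    }
    rec$var_log_e_ratio <- stats::var(lr_e, na.rm = TRUE)
    rec$var_log_c_ratio <- stats::var(lr_c, na.rm = TRUE)
  }
  rec
}

#' Summary of divergence along above-average evolvability directions
#'
#' Across a set of divergence-vector records: the fraction of populations
#' that diverged along directions of above-average evolvability
#' (`e_ratio > 1`) and above-average conditional evolvability
#' (`c_ratio > 1`), and the error-weighed mean log ratios from a mixed model
#' with inverse sampling-variance weights and random intercepts for G-matrix
#' and population identity (degrading to the weighted mean when grouping
#' structure is insufficient). Back-transformed mean ratios are reported.
#'
#' @param records data frame with one row per (G-matrix, population) record:
#'   columns `g_matrix_id`, `population_id`, `e_ratio`, `c_ratio`, and
#'   optionally `var_log_e_ratio`, `var_log_c_ratio`.
#' @return list with `n`, `prop_above_e`, `prop_above_c`,
#'   `mean_log_e_ratio`, `se_log_e_ratio`, `ratio_e` (back-transformed),
#'   and the `c`-counterparts.
#' @export
above_average_summary <- function(records) {
  records <- as.data.frame(records)
  records <- records[is.finite(records$e_ratio), , drop = FALSE]
  if (!nrow(records)) stop("no valid records", call. = FALSE)

  weighted_mean_model <- function(y, v, dat) {
    w <- if (!is.null(v) && any(is.finite(v)) && all(v > 0, na.rm = TRUE)) {
      vv <- v; vv[!is.finite(vv)] <- stats::median(vv[is.finite(vv)])
      1 / vv
    } else rep(1, length(y))
    dat$.y <- y; dat$.wt <- w
    ri <- character()
    for (g in c("g_matrix_id", "population_id"))
      if (g %in% names(dat) && length(unique(dat[[g]])) >= 2)
        ri <- c(ri, g)
    fit <- tryCatch(
      suppressWarnings(meta_lmm(.y ~ 1, data = dat, weights = ".wt",
                                random_intercepts = ri)),
      error = function(e) NULL)
    if (is.null(fit) && length(y) >= 2)
      fit <- meta_lmm(.y ~ 1, data = dat, weights = ".wt")
    if (is.null(fit))
      return(c(mean = y[1], se = NA_real_))
    c(mean = fit$fixed_effects$estimate[1], se = fit$fixed_effects$se[1])
  }

  me <- weighted_mean_model(log(records$e_ratio),
                            records$var_log_e_ratio, records)
  out <- list(n = nrow(records),
              prop_above_e = mean(records$e_ratio > 1),
              mean_log_e_ratio = unname(me["mean"]),
              se_log_e_ratio = unname(me["se"]),
              ratio_e = exp(unname(me["mean"])))
  if ("c_ratio" %in% names(records) && any(is.finite(records$c_ratio))) {
    cc <- records[is.finite(records$c_ratio), , drop = FALSE]
    mc <- weighted_mean_model(log(cc$c_ratio), cc$var_log_c_ratio, cc)
    out$prop_above_c <- mean(cc$c_ratio > 1)
    out$mean_log_c_ratio <- unname(mc["mean"])
    out$se_log_c_ratio <- unname(mc["se"])
    out$ratio_c <- exp(unname(mc["mean"]))
  }
  out
}

#' Per-study divergence vs evolvability-along-divergence table
#'
#' For each divergence study, pairs the divergence magnitude of every
#' record with the evolvability (and conditional evolvability) along its
#' divergence vector, and reports the Spearman rank correlation between
#' magnitude and evolvability — a quantitative proxy for "populations that
#' diverged along directions of greater evolvability diverged farther".
#' Studies with fewer than 3 records get an `NA` correlation.
#'
#' @param records data frame with columns `study_id`, `d_mag`, `e_along`,
#'   and optionally `c_along`.
#' @return list with `table` (the input, ordered by study) and
#'   `correlations` (per-study data frame with `rho_e`, `rho_c`, `n`).
#' @export
divergence_vs_evolvability_table <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("study_id", "d_mag", "e_along") %in% names(records)))
  split_recs <- split(records, records$study_id)
  cors <- lapply(split_recs, function(r) {
    rho_e <- rho_c <- NA_real_
    if (nrow(r) >= 3) {
      rho_e <- suppressWarnings(
        stats::cor(r$d_mag, r$e_along, method = "spearman"))
      if ("c_along" %in% names(r))
        rho_c <- suppressWarnings(
          stats::cor(r$d_mag, r$c_along, method = "spearman"))
    }
    data.frame(study_id = r$study_id[1], rho_e = rho_e, rho_c = rho_c,
               n = nrow(r))
  })
  list(table = records[order(records$study_id), , drop = FALSE],
       correlations = do.call(rbind, c(cors, make.row.names = FALSE)))
}
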