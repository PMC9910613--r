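#' Among-population variance of log population means
#'
#' The core divergence statistic: the sample variance (n-1 denominator) of
#' natural-log-transformed population means for one trait. On the log scale
#' this is a proportional (unit-free) measure of among-population divergence,
#' directly comparable with mean-scaled evolvability.
#'
#' @param means numeric vector of strictly positive population trait means
#'   (length >= 2); names, when present, identify populations in error
#'   messages.
#' @return scalar divergence `d` (variance of log means).
#' @export
among_population_variance <- function(means) {
  if (length(means) < 2)
    stop("need at least 2 population means, got ", length(means),
         call. = FALSE)
  bad <- which(!is.finite(means) | means <= 0)
  if (length(bad)) {
    ids <- names(means)[bad] %||% as.character(bad)
    stop("non-positive population mean(s) for population ",
         paste(ids, collapse = ", "), "; log-scale divergence undefined",
         call. = FALSE)
  }
  stats::var(log(means))
}

#' Proportional divergence factor
#'
#' Back-transforms a log-scale among-population variance `d` to the
#' proportional factor \eqn{d_P = \exp(\sqrt{2d/\pi})}: assuming normal log
#' population means, \eqn{\sqrt{2d/\pi}} is the folded-normal expectation of
#' the absolute log deviation from the grand mean, so the average population
#' mean is `d_P` times larger or `1/d_P` times smaller than the grand mean.
#'
#' @param d non-negative among-population variance of log means.
#' @return proportional divergence factor `d_P >= 1` (vectorized).
#' @export
proportional_divergence <- function(d) {
  if (any(!is.finite(d) | d < 0))
    stop("'d' must be non-negative and finite", call. = FALSE)
  exp(sqrt(2 * d / pi))
}

#' @rdname proportional_divergence
#' @param d_P proportional divergence factor (>= 1) to invert back to `d`.
#' @export
inverse_proportional_divergence <- function(d_P) {
  if (any(!is.finite(d_P) | d_P < 1))
    stop("'d_P' must be >= 1", call. = FALSE)
  log(d_P)^2 * pi / 2
}

#' Measurement-error variance of a divergence estimate
#'
#' The sampling variance of an among-population variance estimated from
#' `n_pop` populations is \eqn{\sigma^2_m(d) = 2 d^2 / (n_{pop} + 2)}. On
#' the log scale the delta method transfers this to the constant
#' \eqn{2 / (n_{pop} + 2)}, which is the default basis for inverse-variance
#' weights when the meta-regression response is `log(d)`.
#'
#' @param d divergence estimate(s), `>= 0`.
#' @param n_pop number of populations behind each estimate (`>= 2`).
#' @param log_scale if `TRUE`, return the delta-method variance of `log(d)`.
#' @return measurement-error variance (vectorized).
#' @export
measurement_error_variance <- function(d, n_pop, log_scale = FALSE) {
  if (any(n_pop < 2)) stop("'n_pop' must be >= 2", call. = FALSE)
  if (any(d < 0)) stop("'d' must be >= 0", call. = FALSE)
  if (log_scale) 2 / (n_pop + 2) else 2 * d^2 / (n_pop + 2)
}

#' Estimate a D-matrix from population trait means
#'
#' Simple sample-covariance estimator of the among-population (ln-scale)
#' variance matrix: the (n-1)-denominator covariance of log population means
#' across populations. Populations with missing trait values are handled per
#' `complete_cases`: by default an error lists them; with
#' `complete_cases = TRUE` they are dropped (listwise) with a message.
#'
#' @param pop_means data frame with columns `population_id`, `trait`, `mean`
#'   restricted to one divergence study.
#' @param trait_subset optional character vector selecting traits.
#' @param complete_cases drop populations with incomplete trait records
#'   instead of erroring.
#' @return a [g_matrix()] holding D, with attribute `n_pops`.
#' @export
estimate_D_matrix <- function(pop_means, trait_subset = NULL,
                              complete_cases = FALSE) {
  req <- c("population_id", "trait", "mean")
  if (!all(req %in% names(pop_means)))
    stop("'pop_means' needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!is.null(trait_subset))
    pop_means <- pop_means[pop_means$trait %in% trait_subset, , drop = FALSE]
  wide <- stats::reshape(
    pop_means[, req], idvar = "population_id", timevar = "trait",
    direction = "wide")
  rownames(wide) <- wide$population_id
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^mean\\.", "", colnames(m))
  if (!is.null(trait_subset)) m <- m[, trait_subset, drop = FALSE]
  incomplete <- rownames(m)[!stats::complete.cases(m)]
  if (length(incomplete)) {
    if (!complete_cases)
      stop("populations with missing trait values: ",
           paste(incomplete, collapse = ", "),
           " (set complete_cases = TRUE to drop them)", call. = FALSE)
    message("estimate_D_matrix: dropped incomplete populations: ",
            paste(incomplete, collapse = ", "))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (nrow(m) < 3)
    stop("need >= 3 complete populations, have ", nrow(m), call. = FALSE)
  if (any(m <= 0))
    stop("non-positive trait means; log transform undefined", call. = FALSE)
  D <- g_matrix(stats::cov(log(m)), sym_tol = 1e-8)
  attr(D, "n_pops") <- nrow(m)
  D
}

#' Divergence vector between two populations
#'
#' The realized direction of evolution between a focal and a target
#' population: \eqn{\Delta = \log(\bar{x}_{target}) - \log(\bar{x}_{focal})}.
#' Its Euclidean norm is the divergence magnitude and its unit direction is
#' the axis along which evolution occurred.
#'
#' @param focal_means,target_means strictly positive named trait-mean
#'   vectors over the same trait set.
#' @return list with `delta` (log-difference vector), `magnitude`
#'   (`||delta||`), and `unit_direction` (or `NA`s when `magnitude == 0`;
#'   downstream operations skip such records).
#' @export
divergence_vector <- function(focal_means, target_means) {
  if (!is.null(names(focal_means)) && !is.null(names(target_means))) {
    if (!setequal(names(focal_means), names(target_means)))
      stop("trait sets of focal and target means differ", call. = FALSE)
    target_means <- target_means[names(focal_means)]
  } else if (length(focal_means) != length(target_means)) {
    stop("mean vectors differ in length", call. = FALSE)
  }
  if (any(focal_means <= 0) || any(target_means <= 0))
    stop("population means must be strictly positive", call. = FALSE)
  delta <- log(target_means) - log(focal_means)
  mag <- sqrt(sum(delta^2))
  unit <- if (mag > 0) delta / mag else delta * NA_real_
  list(delta = delta, magnitude = mag, unit_direction = unit)
}

#' Group medians of proportional divergence with bootstrap SEs
#'
#' Summarizes proportional divergence factors by group: the median per group
#' plus a standard error computed as the SD of medians over seeded
#' nonparametric bootstrap resamples. Groups with a single estimate get
#' `NA` SE; empty groups are dropped with a warning.
#'
#' @param d_P numeric vector of proportional divergence factors.
#' @param group factor/character vector of group labels, same length.
#' @param bootstrap_reps number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return data frame with columns `group`, `median_dP`, `se`, `n`.
#' @export
median_divergence_summary <- function(d_P, group, bootstrap_reps = 2000,
                                      seed = NULL) {
  stopifnot(length(d_P) == length(group))
  keep <- !is.na(d_P) & !is.na(group)
  d_P <- d_P[keep]; group <- as.character(group)[keep]
  lev <- unique(group)
  if (!length(lev)) {
    warning("no non-empty groups", call. = FALSE)
    return(data.frame(group = character(), median_dP = numeric(),
                      se = numeric(), n = integer()))
  }
  with_seed(seed, {
    rows <- lapply(lev, function(g) {
      x <- d_P[group == g]
      se <- NA_real_
      if (length(x) > 1) {
        boot <- replicate(bootstrap_reps,
                          stats::median(sample(x, replace = TRUE)))
        se <- stats::sd(boot)
      }
      data.frame(group = g, median_dP = stats::median(x), se = se,
                 n = length(x))
    })
    do.call(rbind, rows)
  })
}
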