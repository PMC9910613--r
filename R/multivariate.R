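#' Bundle a paired G/D(/P) matrix case
#'
#' A "case" pairs a mean-scaled genetic covariance matrix with the
#' among-population divergence matrix estimated over the same trait set
#' (and optionally a phenotypic matrix whose eigenvectors provide direction
#' sets with estimation error independent of both G and D). At least three
#' traits are required for a meaningful within-case regression.
#'
#' @param case_id identifier.
#' @param G,D [g_matrix()] objects over an identical ordered trait set.
#' @param P optional phenotypic matrix, same trait set.
#' @param species species label.
#' @param d_matrix_id identifier of the divergence matrix (several cases may
#'   share one); defaults to `case_id`.
#' @param n_pops number of populations behind D (defaults to the `n_pops`
#'   attribute of `D`).
#' @return object of class `qg_case`.
#' @export
case_study <- function(case_id, G, D, P = NULL, species = NA_character_,
                       d_matrix_id = case_id, n_pops = NULL) {
  stopifnot(inherits(G, "g_matrix"), inherits(D, "g_matrix"))
  if (!identical(trait_labels(G), trait_labels(D)))
    stop("G and D trait sets differ", call. = FALSE)
  if (!is.null(P) && !identical(trait_labels(G), trait_labels(P)))
    stop("P trait set differs from G/D", call. = FALSE)
  if (nrow(G) < 3)
    stop("cases require >= 3 traits, have ", nrow(G), call. = FALSE)
  structure(list(case_id = case_id, G = G, D = D, P = P, species = species,
                 d_matrix_id = d_matrix_id,
                 n_pops = n_pops %||% attr(D, "n_pops"),
                 k = nrow(G)),
            class = "qg_case")
}

#' @export
print.qg_case <- function(x, ...) {
  cat(sprintf("Case %s: %d traits, species %s, n_pops %s, P %s\n",
              x$case_id, x$k, x$species,
              x$n_pops %||% NA, if (is.null(x$P)) "absent" else "present"))
  invisible(x)
}

#' Focal direction sets for a case
#'
#' Returns the unit directions along which evolvability and divergence are
#' compared: the original trait axes (standard basis vectors, so projections
#' reduce to matrix diagonals and the regression is equivalent to the
#' univariate analysis), or the eigenvectors of the G-, D-, or P-matrix.
#'
#' @param case a [case_study()].
#' @param which one of `"original"`, `"G_eigen"`, `"D_eigen"`, `"P_eigen"`.
#' @return k x k matrix whose columns are unit direction vectors.
#' @export
direction_set <- function(case,
                          which = c("original", "G_eigen", "D_eigen",
                                    "P_eigen")) {
  which <- match.arg(which)
  k <- case$k
  labs <- trait_labels(case$G)
  if (which == "original") {
    V <- diag(k)
    dimnames(V) <- list(labs, labs)
    return(V)
  }
  m <- switch(which, G_eigen = case$G, D_eigen = case$D, P_eigen = case$P)
  if (is.null(m))
    stop("case ", case$case_id, " has no P-matrix; cannot use P_eigen",
         call. = FALSE)
  eigen_directions(m)$vectors
}

#' Within-case evolvability-divergence regression
#'
#' Ordinary least squares of `log d(v)` on `log e(v)` over a direction set,
#' where `e(v) = v'Gv` (or the conditional evolvability `c(v)` when
#' `conditional = TRUE`) and `d(v) = v'Dv`. Directions with non-positive
#' projected variance (possible for estimated, non-PSD matrices) are dropped
#' with a warning and counted.
#'
#' @inheritParams direction_set
#' @param conditional substitute conditional evolvability for evolvability.
#' @param directions optional matrix of direction columns overriding
#'   `which` (used internally for Monte-Carlo draws).
#' @return object of class `case_slope`: list with `slope`, `intercept`,
#'   `r2`, `n_directions`, `n_dropped`, `direction_set`, `conditional`,
#'   `e`, `d` (the per-direction values), plus case identifiers.
#' @export
case_regression <- function(case, which = "original", conditional = FALSE,
                            directions = NULL) {
  V <- directions %||% direction_set(case, which)
  Gm <- as_plain_matrix(case$G)
  Dm <- as_plain_matrix(case$D)
  e <- colSums(V * (Gm %*% V))
  if (conditional) {
    Gi <- solve(Gm)
    e <- 1 / colSums(V * (Gi %*% V))
  }
  d <- colSums(V * (Dm %*% V))
  ok <- e > 0 & d > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(n_dropped, " direction(s) with non-positive projection dropped",
            call. = FALSE)
  if (sum(ok) < 2)
    stop("fewer than 2 usable directions; cannot regress", call. = FALSE)
  x <- log(e[ok]); y <- log(d[ok])
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(case_id = case$case_id, species = case$species,
                 d_matrix_id = case$d_matrix_id,
                 direction_set = if (is.null(directions)) which else "custom",
                 conditional = conditional,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 n_directions = sum(ok), n_dropped = n_dropped,
                 e = e, d = d),
            class = "case_slope")
}

#' @export
print.case_slope <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Case %s [%s%s]: slope %.3f, intercept %.3f, r2 %.3f (%d directions%s)\n",
    x$case_id, x$direction_set, if (x$conditional) ", conditional" else "",
    x$slope, x$intercept, x$r2, x$n_directions,
    if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}

#' Monte-Carlo resampling of a G-matrix
#'
#' Emulates the sampling distribution of an estimated G-matrix: each
#' iteration draws `n_families` observations from a multivariate normal with
#' mean vector 1 (the mean after mean-scaling) and covariance `G`, and
#' returns their sample covariance. The draws are elementwise unbiased for
#' `G` but the leading eigenvalue of each draw is upwardly biased — the
#' sampling artefact that inflates D-direction slopes and deflates
#' G-direction slopes downstream.
#'
#' @param G a [g_matrix()] with a finite `n_families` attribute (or supply
#'   `n_families`).
#' @param iters number of resampled matrices.
#' @param seed optional integer seed.
#' @param n_families override for the effective sample size.
#' @return list of `iters` plain k x k covariance matrices.
#' @export
resample_G <- function(G, iters = 1000, seed = NULL, n_families = NULL) {
  n <- n_families %||% attr(G, "n_families")
  if (is.null(n) || is.na(n) || n < 2)
    stop("valid 'n_families' required for resampling", call. = FALSE)
  k <- nrow(G)
  if (n < k + 1)
    warning("n_families < k + 1: resampled matrices will be singular",
            call. = FALSE)
  Gm <- as_plain_matrix(G)
  ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("G is not positive semi-definite", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(iters), function(i) {
      x <- MASS::mvrnorm(n, mu = rep(1, k), Sigma = Gm)
      stats::cov(x)
    })
  })
}

#' Wishart approximation to the sampling distribution of a D-matrix
#'
#' When only a point estimate of D is available, draws are generated from a
#' Wishart distribution with effective degrees of freedom `n_pops - 1`,
#' scaled so the draws are elementwise unbiased for D. This approximates the
#' sampling distribution of a sample covariance over `n_pops` populations.
#'
#' @param D a [g_matrix()] divergence matrix.
#' @param n_pops number of populations behind D (defaults to its attribute).
#' @param iters number of draws.
#' @param seed optional integer seed.
#' @return list of plain k x k matrices.
#' @export
resample_D <- function(D, n_pops = NULL, iters = 1000, seed = NULL) {
  n <- n_pops %||% attr(D, "n_pops")
  if (is.null(n) || is.na(n) || n < 2)
    stop("valid 'n_pops' required", call. = FALSE)
  Dm <- as_plain_matrix(D)
  # sample covariance of n MVN draws: Wishart(n-1, D/(n-1)), elementwise
  # unbiased for D, and well-defined (singular) even when n - 1 < k
  with_seed(seed, {
    lapply(seq_len(iters), function(i) {
      x <- MASS::mvrnorm(n, mu = rep(0, nrow(Dm)), Sigma = Dm)
      stats::cov(x)
    })
  })
}

#' Monte-Carlo SE of a within-case slope
#'
#' The SE of an evolvability-divergence slope is the SD of slopes across
#' randomly paired draws from the sampling distributions of G and D.
#' Directions are recomputed from the drawn matrix named by `which` for each
#' pairing (set `fixed_directions = TRUE` to hold them at the point-estimate
#' directions for sensitivity analysis). Pairings where the regression fails
#' (non-positive projections on more than k-2 directions) are dropped and
#' counted; more than 50% dropped is an error.
#'
#' @inheritParams case_regression
#' @param G_draws,D_draws lists of matrices from [resample_G()] /
#'   [resample_D()] (>= 100 draws each recommended).
#' @param pairings number of random (G, D) pairs.
#' @param seed optional integer seed.
#' @param fixed_directions keep point-estimate directions across draws.
#' @return list with `se`, `slopes` (per-pairing values), `n_dropped`.
#' @export
slope_se <- function(case, which = "original", G_draws, D_draws,
                     pairings = 1000, seed = NULL, conditional = FALSE,
                     fixed_directions = FALSE) {
  if (length(G_draws) < 2 || length(D_draws) < 2)
    stop("need draw lists for both G and D", call. = FALSE)
  labs <- trait_labels(case$G)
  fixed_V <- if (fixed_directions) direction_set(case, which) else NULL
  with_seed(seed, {
    gi <- sample.int(length(G_draws), pairings, replace = TRUE)
    di <- sample.int(length(D_draws), pairings, replace = TRUE)
    slopes <- rep(NA_real_, pairings)
    for (j in seq_len(pairings)) {
      Gd <- g_matrix(G_draws[[gi[j]]], trait_labels = labs, sym_tol = 1e-6)
      Dd <- g_matrix(D_draws[[di[j]]], trait_labels = labs, sym_tol = 1e-6)
      cs <- list(case_id = case$case_id, species = case$species,
                 d_matrix_id = case$d_matrix_id, G = Gd, D = Dd, P = case$P,
                 n_pops = case$n_pops, k = case$k)
      class(cs) <- "qg_case"
      res <- tryCatch(
        suppressWarnings(case_regression(
          cs, which, conditional = conditional, directions = fixed_V)),
        error = function(e) NULL)
      if (!is.null(res)) slopes[j] <- res$slope
    }
    n_dropped <- sum(is.na(slopes))
    if (n_dropped > pairings / 2)
      stop("more than 50% of draw pairings degenerate (",
           n_dropped, "/", pairings, ")", call. = FALSE)
    list(se = stats::sd(slopes, na.rm = TRUE),
         slopes = slopes, n_dropped = n_dropped)
  })
}

#' Error-weighed grand slope across cases
#'
#' Meta-analytic summary of within-case slopes for one direction set: a
#' mixed model with the case slopes as response, inverse sampling-variance
#' weights (`1/se^2`), and random intercepts for species and for D-matrix
#' identity. With too few groups for the random terms (or a singular fit)
#' the model degrades gracefully towards the weighted mean. When all SEs
#' are missing, equal weights are used with a warning.
#'
#' @param results data frame with columns `slope`, `se`, `species`,
#'   `d_matrix_id` (and optionally `r2`), one row per case.
#' @return list with `slope`, `se`, `median_r2`, `n_cases`, and the
#'   underlying `fit` (`NULL` when n = 1).
#' @export
meta_slope <- function(results) {
  results <- as.data.frame(results)
  stopifnot(all(c("slope", "se", "species", "d_matrix_id") %in%
                  names(results)))
  n <- nrow(results)
  med_r2 <- if ("r2" %in% names(results))
    stats::median(results$r2, na.rm = TRUE) else NA_real_
  if (n == 0) stop("no case results", call. = FALSE)
  if (all(is.na(results$se)) || any(results$se == 0, na.rm = TRUE)) {
    if (all(is.na(results$se)))
      warning("no slope SEs available; using equal weights", call. = FALSE)
    w <- rep(1, n)
  } else {
    se <- results$se
    se[is.na(se)] <- stats::median(se, na.rm = TRUE)
    w <- 1 / se^2
  }
  if (n == 1)
    return(list(slope = results$slope, se = results$se,
                median_r2 = med_r2, n_cases = 1L, fit = NULL))
  ri <- character()
  if (length(unique(results$species)) >= 2) ri <- c(ri, "species")
  if (length(unique(results$d_matrix_id)) >= 2) ri <- c(ri, "d_matrix_id")
  results$.wt <- w
  fit <- tryCatch(
    suppressWarnings(meta_lmm(slope ~ 1, data = results, weights = ".wt",
                              random_intercepts = ri)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- suppressWarnings(meta_lmm(slope ~ 1, data = results,
                                     weights = ".wt"))
  list(slope = fit$fixed_effects$estimate[1],
       se = fit$fixed_effects$se[1],
       median_r2 = med_r2, n_cases = n, fit = fit)
}
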