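#' Evolvability along a phenotypic direction
#'
#' The evolvability along a unit-length direction `v` is \eqn{e(v) = v'Gv}:
#' the predicted proportional response to a unit-strength selection gradient
#' along `v`. Non-unit inputs are normalized (with a warning beyond 1e-8
#' deviation).
#'
#' @param G a [g_matrix()] (mean-scaled genetic covariance matrix).
#' @param v numeric direction vector, optionally named by trait.
#' @return scalar evolvability (dimensionless, proportional scale).
#' @seealso [conditional_evolvability_along()], [project_divergence()]
#' @export
evolvability_along <- function(G, v) {
  v <- normalize_direction(align_direction(v, G))
  drop(crossprod(v, as_plain_matrix(G) %*% v))
}

#' Conditional evolvability along a phenotypic direction
#'
#' The conditional evolvability \eqn{c(v) = (v'G^{-1}v)^{-1}} is the expected
#' response along `v` when selection holds all orthogonal trait combinations
#' constant; it is a lower bound on the response, with \eqn{c(v) \le e(v)}
#' and equality exactly when `v` is an eigenvector of `G`.
#'
#' Ill-conditioned matrices are rejected rather than pseudo-inverted: a
#' silent regularization would bias `c` downward invisibly. Reduce the trait
#' set instead.
#'
#' @inheritParams evolvability_along
#' @param rcond_tol minimum reciprocal condition number accepted.
#' @return scalar conditional evolvability.
#' @export
conditional_evolvability_along <- function(G, v, rcond_tol = 1e-12) {
  v <- normalize_direction(align_direction(v, G))
  Gm <- as_plain_matrix(G)
  sv <- svd(Gm, nu = 0, nv = 0)$d
  if (min(sv) / max(sv) < rcond_tol)
    stop("G is singular or ill-conditioned (rcond = ",
         signif(min(sv) / max(sv), 3),
         "); consider reducing the trait set", call. = FALSE)
  1 / drop(crossprod(v, solve(Gm, v)))
}

#' Divergence along a phenotypic direction
#'
#' Projects an among-population (ln-scale) variance matrix `D` onto a unit
#' direction: \eqn{d(v) = v'Dv}, the proportional among-population variance
#' along `v`.
#'
#' @param D a [g_matrix()] holding the D-matrix.
#' @inheritParams evolvability_along
#' @return scalar divergence along `v`.
#' @export
project_divergence <- function(D, v) evolvability_along(D, v)

#' Eigen-decomposition with a reproducible sign convention
#'
#' Returns eigenvalues in descending order with orthonormal eigenvectors
#' whose largest-magnitude coefficient is positive (the sign of an
#' eigenvector is arbitrary; fixing it makes outputs reproducible).
#'
#' @param m symmetric matrix ([g_matrix()] or plain).
#' @return list with `values` (descending numeric vector) and `vectors`
#'   (matrix whose columns are unit eigenvectors, rows labeled by trait).
#' @export
eigen_directions <- function(m) {
  labs <- rownames(m) %||% paste0("t", seq_len(nrow(m)))
  mm <- if (inherits(m, "g_matrix")) as_plain_matrix(m) else as.matrix(m)
  if (max(abs(mm - t(mm))) > 1e-8 * max(abs(mm), 1e-300))
    stop("eigen_directions requires a symmetric matrix", call. = FALSE)
  e <- eigen((mm + t(mm)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(labs, paste0("ev", seq_len(ncol(V))))
  list(values = e$values, vectors = V)
}

#' Summary evolvabilities of a G-matrix
#'
#' Computes the mean evolvability \eqn{\bar{e} = \mathrm{tr}(G)/k} (the
#' average of `e(v)` over uniformly distributed directions), the minimum and
#' maximum evolvabilities (smallest/largest eigenvalues, attained along the
#' trailing/leading eigenvectors), and the mean conditional evolvability
#' \eqn{\bar{c}}, estimated by seeded Monte Carlo over uniform random unit
#' directions. For singular matrices \eqn{\bar{c}} is reported as `NA` while
#' the other summaries are still returned.
#'
#' @param G a [g_matrix()].
#' @param mc_samples number of random directions for \eqn{\bar{c}}.
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param rcond_tol passed to the conditional-evolvability inversion.
#' @return object of class `gmat_summary`: list with `e_mean`, `c_mean`,
#'   `e_min`, `e_max`, `eigenvalues` (descending), `mc_samples`.
#' @export
matrix_summary <- function(G, mc_samples = 10000, seed = NULL,
                           rcond_tol = 1e-12) {
  Gm <- as_plain_matrix(G)
  k <- nrow(Gm)
  ev <- eigen_directions(Gm)$values
  e_mean <- sum(diag(Gm)) / k
  sv <- svd(Gm, nu = 0, nv = 0)$d
  c_mean <- NA_real_
  if (min(sv) / max(sv) >= rcond_tol) {
    Ginv <- solve(Gm)
    c_mean <- with_seed(seed, {
      U <- random_unit_vectors(mc_samples, k)
      mean(1 / rowSums((U %*% Ginv) * U))
    })
  }
  structure(list(e_mean = e_mean, c_mean = c_mean,
                 e_min = min(ev), e_max = max(ev),
                 eigenvalues = ev, mc_samples = mc_samples),
            class = "gmat_summary")
}

#' @export
print.gmat_summary <- function(x, digits = 4, ...) {
  cat("G-matrix evolvability summary\n")
  cat(sprintf("  mean e:        %.*g\n", digits, x$e_mean))
  cat(sprintf("  mean c (MC):   %.*g  (%d directions)\n", digits,
              x$c_mean, x$mc_samples))
  cat(sprintf("  min/max e:     %.*g / %.*g\n", digits, x$e_min,
              digits, x$e_max))
  invisible(x)
}

#' Scale a value between matrix mean and extreme evolvabilities
#'
#' Display scaling used for divergence-vector panels: a value equal to the
#' matrix mean maps to 0, the maximum to +1, the minimum to -1, with linear
#' interpolation on each side. Values outside `[e_min, e_max]` are clamped
#' with a warning; a degenerate matrix (`e_min == e_max`) maps to 0.
#'
#' @param value evolvability (or conditional evolvability) to scale.
#' @param mean_value the matrix mean to center on (`e_mean` or `c_mean`).
#' @param e_min,e_max extreme evolvabilities of the matrix.
#' @return scaled value in `[-1, 1]`.
#' @export
minmax_scale <- function(value, mean_value, e_min, e_max) {
  if (e_max <= e_min) return(rep(0, length(value)))
  out <- value
  clamp <- value < e_min | value > e_max
  if (any(clamp)) {
    warning(sum(clamp), " value(s) outside [e_min, e_max] clamped",
            call. = FALSE)
    out <- pmin(pmax(value, e_min), e_max)
  }
  ifelse(out >= mean_value,
         (out - mean_value) / (e_max - mean_value),
         (out - mean_value) / (mean_value - e_min))
}
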