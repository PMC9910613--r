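#' Construct a labeled mean-scaled (co)variance matrix
#'
#' A `g_matrix` holds a symmetric mean-scaled (co)variance matrix with trait
#' labels and, for genetic matrices, the effective number of families of the
#' breeding design. The same container is used for among-population
#' divergence matrices (D) and phenotypic matrices (P); only the
#' interpretation differs.
#'
#' Mean-scaled genetic variances (evolvability, \eqn{I_A = V_A / \bar{x}^2})
#' are dimensionless, so entries are directly comparable across traits.
#'
#' @param values square numeric matrix of mean-scaled (co)variances.
#' @param trait_labels character vector of unique trait names; defaults to
#'   the dimnames of `values`.
#' @param n_families effective sample size (number of families) behind the
#'   estimate, or `NA` when unknown/irrelevant (e.g. for D-matrices).
#' @param species,study_id optional identifiers carried as attributes.
#' @param sym_tol relative tolerance for the symmetry check.
#' @return an object of class `g_matrix` (a numeric matrix with attributes).
#' @export
g_matrix <- function(values, trait_labels = NULL, n_families = NA_integer_,
                     species = NA_character_, study_id = NA_character_,
                     sym_tol = 1e-10) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("'values' must be square", call. = FALSE)
  k <- nrow(values)
  if (is.null(trait_labels)) trait_labels <- rownames(values)
  if (is.null(trait_labels)) trait_labels <- paste0("t", seq_len(k))
  if (length(trait_labels) != k || anyDuplicated(trait_labels))
    stop("'trait_labels' must be ", k, " unique names", call. = FALSE)
  scale <- max(abs(values), 1e-300)
  if (max(abs(values - t(values))) / scale > sym_tol)
    stop("matrix is not symmetric within tolerance ", sym_tol, call. = FALSE)
  values <- (values + t(values)) / 2
  if (any(diag(values) < 0))
    stop("negative diagonal entries: ",
         paste(trait_labels[diag(values) < 0], collapse = ", "),
         call. = FALSE)
  dimnames(values) <- list(trait_labels, trait_labels)
  structure(values,
            n_families = n_families, species = species, study_id = study_id,
            class = c("g_matrix", "matrix", "array"))
}

#' @export
print.g_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Mean-scaled (co)variance matrix (%d traits)\n", nrow(x)))
  nf <- attr(x, "n_families")
  if (!is.na(nf)) cat("  effective families:", nf, "\n")
  sp <- attr(x, "species")
  if (!is.na(sp)) cat("  species:", sp, "\n")
  print(round(unclass(x)[,], digits), ...)
  invisible(x)
}

trait_labels <- function(x) rownames(x)

# strip g_matrix attributes -> plain matrix
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  y
}

#' Mean-scale a raw covariance matrix
#'
#' Converts a covariance matrix in squared trait units to the dimensionless
#' proportional scale by dividing each entry by the product of the
#' corresponding trait means: `out[i,j] = raw[i,j] / (means[i] * means[j])`.
#' For a genetic covariance matrix this yields the evolvability matrix whose
#' diagonal entries are \eqn{I_A = V_A/\bar{x}^2}.
#'
#' @param raw_cov symmetric covariance matrix in trait units squared.
#' @param means strictly positive trait means, same order as `raw_cov`.
#' @param ... passed to [g_matrix()] (labels, `n_families`, identifiers).
#' @return a [g_matrix()].
#' @export
mean_scale_covariance <- function(raw_cov, means, ...) {
  raw_cov <- as.matrix(raw_cov)
  if (length(means) != nrow(raw_cov))
    stop("'means' length must match matrix dimension", call. = FALSE)
  labs <- rownames(raw_cov) %||% names(means) %||%
    paste0("t", seq_along(means))
  bad <- which(!is.finite(means) | means <= 0)
  if (length(bad))
    stop("mean-scaling undefined: non-positive mean for trait ",
         paste(labs[bad], collapse = ", "), call. = FALSE)
  g_matrix(raw_cov / tcrossprod(means), trait_labels = labs, ...)
}

#' Read / write a square labeled matrix as CSV
#'
#' Plain-text exchange format for G-, D-, and P-matrices: first row and first
#' column carry the trait labels. On reading, asymmetries up to `sym_tol`
#' (relative to the largest entry) are averaged out, and the maximum
#' asymmetry found is reported via `message()`.
#'
#' @param path file path.
#' @param sym_tol relative symmetry tolerance accepted on read.
#' @param ... passed to [g_matrix()].
#' @return `read_matrix_csv()` returns a [g_matrix()];
#'   `write_matrix_csv()` returns `path` invisibly.
#' @export
read_matrix_csv <- function(path, sym_tol = 1e-8, ...) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ in ", path, call. = FALSE)
  asym <- max(abs(m - t(m))) / max(abs(m), 1e-300)
  if (asym > sym_tol)
    stop("matrix in ", path, " asymmetric beyond tolerance (rel. asymmetry ",
         signif(asym, 3), ")", call. = FALSE)
  if (asym > 0)
    message("read_matrix_csv: averaged asymmetry of relative magnitude ",
            signif(asym, 3))
  g_matrix((m + t(m)) / 2, sym_tol = Inf, ...)
}

#' @rdname read_matrix_csv
#' @param m matrix (or [g_matrix()]) to write.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as_plain_matrix(m), path, row.names = TRUE)
  invisible(path)
}

# Normalize a direction vector to unit length; warn when the input deviates
# from unit length by more than `tol` (auto-normalization is logged, not
# silent, so accidental unnormalized inputs are visible).
normalize_direction <- function(v, tol = 1e-8) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length direction vector", call. = FALSE)
  if (abs(nv - 1) > tol)
    warning(sprintf("direction vector normalized (length was %.6g)", nv),
            call. = FALSE)
  v / nv
}

# Align a direction vector with a matrix's trait set. Named vectors are
# reordered to the matrix order; unnamed vectors must match the dimension.
align_direction <- function(v, m) {
  labs <- trait_labels(m)
  if (!is.null(names(v))) {
    if (!setequal(names(v), labs))
      stop("trait labels of direction vector do not match matrix: [",
           paste(names(v), collapse = ","), "] vs [",
           paste(labs, collapse = ","), "]", call. = FALSE)
    v <- v[labs]
  } else if (length(v) != nrow(m)) {
    stop("direction vector length ", length(v),
         " does not match matrix dimension ", nrow(m), call. = FALSE)
  }
  as.numeric(v)
}
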