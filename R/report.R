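#' Write and read a simulation configuration as key: value text
#'
#' Plain-text serialization of a [sim_config()]: one `key: value` line per
#' scalar field (vector fields comma-separated). Lines starting with `#`
#' and blank lines are ignored on read.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lines <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    val <- if (is.numeric(v)) paste(format(v, digits = 15), collapse = ",")
    else paste(as.character(v), collapse = ",")
    if (!is.null(names(v)) && length(names(v)))
      val <- paste(sprintf("%s=%s", names(v), format(v, digits = 15)),
                   collapse = ",")
    sprintf("%s: %s", nm, val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  args <- list()
  for (m in kv) {
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (all(grepl("=", parts))) {
      nmv <- do.call(rbind, strsplit(parts, "=", fixed = TRUE))
      v <- stats::setNames(as.numeric(nmv[, 2]), trimws(nmv[, 1]))
    } else {
      v <- suppressWarnings(as.numeric(parts))
      if (anyNA(v)) v <- parts
      if (is.character(v) && all(v %in% c("TRUE", "FALSE")))
        v <- as.logical(v)
    }
    args[[key]] <- v
  }
  do.call(sim_config, args)
}

#' Serialize a meta-regression fit to CSV plus a text log
#'
#' Writes the fixed effects (estimates and SEs) as CSV and a short
#' human-readable log (model structure, random components, fit statistics)
#' alongside it.
#'
#' @param fit a [meta_lmm()].
#' @param path_prefix files are written as `<path_prefix>_fixed.csv` and
#'   `<path_prefix>_log.txt`.
#' @return invisible character vector of the two paths.
#' @export
write_fit_report <- function(fit, path_prefix) {
  stopifnot(inherits(fit, "meta_lmm"))
  csv <- paste0(path_prefix, "_fixed.csv")
  log <- paste0(path_prefix, "_log.txt")
  utils::write.csv(fit$fixed_effects, csv, row.names = FALSE)
  txt <- utils::capture.output(summary(fit))
  writeLines(txt, log)
  invisible(c(csv, log))
}

#' Run every analysis on a database and bundle the results
#'
#' Orchestrates the four analyses — divergence patterns, univariate
#' meta-regression, multivariate case analysis, divergence vectors — plus
#' the d/e diagnostic, and attaches a provenance block (seed, package
#' version, and the generating configuration when present) from which the
#' report can be reproduced exactly.
#'
#' @param db a database.
#' @param seed master seed for all Monte-Carlo components.
#' @param iters,pairings Monte-Carlo sizes passed to the multivariate and
#'   divergence-vector stages.
#' @param bootstrap_reps bootstrap resamples for the pattern medians.
#' @return object of class `analysis_report`: list with `patterns`,
#'   `univariate`, `multivariate`, `divergence_vectors`, `de_ratio`,
#'   `provenance`.
#' @export
run_report <- function(db, seed = 1, iters = 200, pairings = 200,
                       bootstrap_reps = 1000) {
  seeds <- child_seeds(seed, 4)
  structure(list(
    patterns = run_patterns(db, bootstrap_reps = bootstrap_reps,
                            seed = seeds[[1]]),
    univariate = suppressWarnings(run_univariate(db)),
    multivariate = run_multivariate(db, iters = iters, pairings = pairings,
                                    seed = seeds[[2]]),
    divergence_vectors = run_divergence_vectors(db, iters = iters,
                                                seed = seeds[[3]]),
    de_ratio = compute_de_ratio(db),
    provenance = list(
      seed = seed, iters = iters, pairings = pairings,
      bootstrap_reps = bootstrap_reps,
      package_version = as.character(utils::packageVersion("qgdiverge")),
      config = db$config)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("==== Analysis report ====\n\n")
  tc <- x$patterns$summaries$trait_category
  if (!is.null(tc)) {
    cat("Median proportional divergence by trait category:\n")
    print(tc, row.names = FALSE)
    cat("\n")
  }
  print(x$univariate); cat("\n")
  print(x$multivariate); cat("\n")
  print(x$divergence_vectors); cat("\n")
  cat(sprintf("Mean d/e ratio: %.3f (median %.3f)\n",
              x$de_ratio$mean, x$de_ratio$median))
  cat(sprintf("Provenance: seed %s, version %s\n",
              x$provenance$seed, x$provenance$package_version))
  invisible(x)
}
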