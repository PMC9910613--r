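#' Weighted mixed-effects meta-regression
#'
#' Fits the Gaussian linear mixed model used throughout the package's
#' meta-analyses: fixed effects given by `fixed`, random intercepts for each
#' grouping factor in `random_intercepts`, and optionally an (uncorrelated)
#' random slope for one covariate within one grouping factor. Observation
#' weights enter in the meta-analytic sense, scaling the residual variance
#' as \eqn{\sigma^2 / w_i}; inverse error-variance weights therefore give
#' each estimate its proper precision.
#'
#' With no random terms the model reduces exactly to (weighted) least
#' squares. Estimation is by maximum likelihood by default so that AIC
#' comparisons across fixed-effect structures are valid; use
#' `method = "REML"` only for final variance reporting.
#'
#' Singular (boundary) random-effect fits are reported with
#' `boundary = TRUE` rather than hidden; true optimizer non-convergence
#' sets `converged = FALSE`.
#'
#' @param fixed two-sided formula for the fixed effects, e.g.
#'   `log_d ~ log_e + log_npop`.
#' @param data data frame containing all variables.
#' @param weights optional numeric vector (or name of a column in `data`) of
#'   strictly positive weights; `NULL` for equal weights.
#' @param random_intercepts character vector of grouping-factor column
#'   names receiving random intercepts (each needs >= 2 levels).
#' @param random_slope optional `c(term, group)`: random slope for `term`
#'   varying by `group`, uncorrelated with the group intercept.
#' @param method `"ML"` (default) or `"REML"`.
#' @return object of class `meta_lmm`; see Details. Components include
#'   `fixed_effects` (data frame of estimates and SEs), `random_components`
#'   (named variances, plus `slope_sd`), `sigma2`, `log_likelihood`, `aic`,
#'   `n_parameters`, `r2_marginal`, `r2_conditional`, `n_obs`, `converged`,
#'   `boundary`, and the underlying `fit` (`lm` or `merMod`).
#' @export
meta_lmm <- function(fixed, data, weights = NULL,
                     random_intercepts = character(),
                     random_slope = NULL, method = c("ML", "REML")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (is.character(weights) && length(weights) == 1L)
    weights <- data[[weights]]
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be strictly positive and finite", call. = FALSE)
  data$.w <- weights

  for (g in c(random_intercepts, random_slope[2])) {
    if (!g %in% names(data)) stop("grouping column '", g, "' not in data",
                                  call. = FALSE)
    if (length(unique(data[[g]])) < 2)
      stop("random term grouping '", g, "' has < 2 levels", call. = FALSE)
  }

  re_terms <- c(
    sprintf("(1 | %s)", random_intercepts),
    if (!is.null(random_slope))
      sprintf("(0 + %s | %s)", random_slope[1], random_slope[2]))
  has_re <- length(re_terms) > 0

  if (!has_re) {
    fit <- stats::lm(fixed, data = data, weights = .w)
    X <- stats::model.matrix(fit)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient fixed-effect design; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    sm <- summary(fit)
    beta <- stats::coef(fit)
    fe <- data.frame(term = names(beta), estimate = unname(beta),
                     se = unname(sm$coefficients[, "Std. Error"]))
    p <- length(beta) + 1L
    ll <- as.numeric(stats::logLik(fit))
    sigma2 <- sum(stats::residuals(fit)^2 * data$.w) / stats::df.residual(fit)
    rc <- numeric(0)
    converged <- TRUE; boundary <- FALSE
  } else {
    form <- stats::as.formula(
      paste(deparse(fixed), "+", paste(re_terms, collapse = " + ")))
    fit <- lme4::lmer(form, data = data, weights = .w,
                      REML = (method == "REML"),
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = TRUE))
    X <- lme4::getME(fit, "X")
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient fixed-effect design", call. = FALSE)
    sm <- summary(fit)
    fe <- data.frame(term = rownames(sm$coefficients),
                     estimate = sm$coefficients[, "Estimate"],
                     se = sm$coefficients[, "Std. Error"],
                     row.names = NULL)
    ll <- as.numeric(stats::logLik(fit))
    p <- attr(stats::logLik(fit), "df")
    vc <- lme4::VarCorr(fit)
    rc <- vapply(vc, function(m) m[1, 1], numeric(1))
    names(rc) <- names(vc)
    sigma2 <- stats::sigma(fit)^2
    boundary <- lme4::isSingular(fit)
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", unlist(msgs %||% "")))
    if (boundary)
      warning("random-effects covariance at boundary (singular fit)",
              call. = FALSE)
    if (!converged)
      warning("optimizer did not converge; inspect the fit", call. = FALSE)
  }

  beta <- fe$estimate
  var_fixed <- stats::var(drop(X %*% beta))
  var_resid <- sigma2 * mean(1 / data$.w)
  var_random <- 0
  slope_sd <- NA_real_
  if (has_re) {
    # variance contributed by random effects at the observed covariate
    # distribution: intercept terms contribute their variance; an
    # uncorrelated random slope tau^2 for covariate z contributes
    # tau^2 * mean(z^2).
    vc <- lme4::VarCorr(fit)
    for (i in seq_along(vc)) {
      nm <- rownames(vc[[i]])
      if (identical(nm, "(Intercept)")) {
        var_random <- var_random + vc[[i]][1, 1]
      } else {
        z <- data[[nm[1]]]
        var_random <- var_random + vc[[i]][1, 1] * mean(z^2)
        slope_sd <- sqrt(vc[[i]][1, 1])
      }
    }
  }
  tot <- var_fixed + var_random + var_resid
  r2m <- if (tot > 0) var_fixed / tot else NA_real_
  r2c <- if (tot > 0) (var_fixed + var_random) / tot else NA_real_

  structure(list(
    call = match.call(), formula = fixed,
    random_intercepts = random_intercepts, random_slope = random_slope,
    method = method, fit = fit,
    fixed_effects = fe, random_components = rc, slope_sd = slope_sd,
    sigma2 = sigma2, log_likelihood = ll, n_parameters = p,
    aic = -2 * ll + 2 * p,
    r2_marginal = r2m, r2_conditional = r2c,
    var_components = c(fixed = var_fixed, random = var_random,
                       residual = var_resid),
    n_obs = nrow(data), converged = converged, boundary = boundary),
    class = "meta_lmm")
}

#' @export
print.meta_lmm <- function(x, digits = 3, ...) {
  cat("Weighted mixed-effects meta-regression (", x$method, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  if (length(x$random_intercepts))
    cat("  random intercepts:", paste(x$random_intercepts, collapse = ", "),
        "\n")
  if (!is.null(x$random_slope))
    cat("  random slope:", x$random_slope[1], "|", x$random_slope[2], "\n")
  fe <- x$fixed_effects
  cat("\nFixed effects:\n")
  print(data.frame(term = fe$term,
                   estimate = signif(fe$estimate, digits),
                   se = signif(fe$se, digits)), row.names = FALSE)
  cat(sprintf("\nAIC %.2f | logLik %.2f | n = %d | r2_M %.3f | r2_C %.3f\n",
              x$aic, x$log_likelihood, x$n_obs,
              x$r2_marginal, x$r2_conditional))
  if (x$boundary) cat("note: singular (boundary) random-effects fit\n")
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.meta_lmm <- function(object, ...) {
  print(object)
  if (length(object$random_components)) {
    cat("\nRandom-effect variances:\n")
    print(signif(object$random_components, 4))
    if (!is.na(object$slope_sd))
      cat(sprintf("random-slope SD: %.4g\n", object$slope_sd))
  }
  cat(sprintf("residual sigma2: %.4g\n", object$sigma2))
  invisible(object)
}

#' @export
coef.meta_lmm <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @export
logLik.meta_lmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_obs, class = "logLik")
}

#' @export
predict.meta_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = newdata, re.form = NA, ...)
}

#' Marginal and conditional r-squared of a meta-regression fit
#'
#' Variance-explained summaries for mixed models: the marginal r2 is the
#' share of total variance attributable to the fixed effects,
#' \eqn{r^2_M = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)}; the
#' conditional r2 adds the random-effect variance to the numerator. The
#' random-slope contribution is evaluated at the observed covariate
#' distribution, and the weighted residual variance is summarized as
#' \eqn{\sigma^2 \cdot \mathrm{mean}(1/w_i)}.
#'
#' @param fit a [meta_lmm()] object.
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "meta_lmm"))
  if (!fit$converged)
    stop("r2 undefined for a non-converged fit", call. = FALSE)
  if (sum(fit$var_components) <= 0)
    stop("zero total variance; r2 undefined", call. = FALSE)
  c(r2_marginal = fit$r2_marginal, r2_conditional = fit$r2_conditional)
}

#' Attenuation correction for estimation error in the predictor
#'
#' Estimation error in the predictor of a regression biases the slope toward
#' zero by the reliability factor \eqn{1 - V_{me}/V}, where \eqn{V_{me}} is
#' the error variance in the predictor and \eqn{V} the total predictor
#' variance. The corrected slope divides the raw slope (and its SE) by the
#' reliability.
#'
#' @param raw_slope estimated (attenuated) slope.
#' @param V_me error variance of the predictor (`0 <= V_me < V`).
#' @param V total variance of the predictor.
#' @param se optional SE of the raw slope, corrected the same way.
#' @return list with `corrected`, `reliability`, and (if `se` given)
#'   `se_corrected`.
#' @export
attenuation_correct <- function(raw_slope, V_me, V, se = NULL) {
  stop_if_not_scalar(raw_slope, "raw_slope")
  if (!is.finite(V_me) || V_me < 0)
    stop("'V_me' must be >= 0", call. = FALSE)
  if (!is.finite(V) || V <= 0) stop("'V' must be > 0", call. = FALSE)
  if (V_me >= V)
    stop("V_me >= V: the predictor is all estimation error; ",
         "attenuation correction undefined", call. = FALSE)
  rel <- 1 - V_me / V
  out <- list(corrected = raw_slope / rel, reliability = rel)
  if (!is.null(se)) out$se_corrected <- se / rel
  out
}

#' AIC comparison of a baseline against a more complex model
#'
#' Returns \eqn{\Delta AIC = AIC_{complex} - AIC_{baseline}}: positive
#' values support the baseline over the more complex model, with
#' `|dAIC| > 2` taken as a detectable difference.
#'
#' @param fit_baseline,fit_complex [meta_lmm()] fits of the same response
#'   rows, both by ML.
#' @return list with `delta_aic` and `support` label
#'   (`"baseline"`, `"complex"`, or `"indistinguishable"`).
#' @export
compare_aic <- function(fit_baseline, fit_complex) {
  stopifnot(inherits(fit_baseline, "meta_lmm"),
            inherits(fit_complex, "meta_lmm"))
  if (fit_baseline$method != "ML" || fit_complex$method != "ML")
    stop("AIC comparison across fixed-effect structures requires ML fits",
         call. = FALSE)
  if (fit_baseline$n_obs != fit_complex$n_obs)
    stop("fits use different numbers of observations", call. = FALSE)
  d <- fit_complex$aic - fit_baseline$aic
  support <- if (d > 2) "baseline" else if (d < -2) "complex"
  else "indistinguishable"
  list(delta_aic = d, support = support)
}

#' Express a log-log slope as percent change in the response
#'
#' For a power-law (log-log) relationship with exponent `slope`, a
#' `pct_increase` percent increase in the predictor changes the response by
#' `100 * ((1 + pct_increase/100)^slope - 1)` percent.
#'
#' @param slope log-log regression slope.
#' @param pct_increase percent increase in the predictor (> -100).
#' @return percent change in the response.
#' @export
slope_to_percent <- function(slope, pct_increase) {
  if (any(pct_increase <= -100))
    stop("'pct_increase' must be > -100", call. = FALSE)
  100 * ((1 + pct_increase / 100)^slope - 1)
}

#' Back-transform a log ratio to a ratio
#'
#' @param log_ratio natural-log ratio (e.g. an error-weighed mean log
#'   evolvability ratio).
#' @return `exp(log_ratio)`.
#' @export
backtransform_log_ratio <- function(log_ratio) {
  if (any(!is.finite(log_ratio))) stop("non-finite input", call. = FALSE)
  exp(log_ratio)
}
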