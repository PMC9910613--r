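#' Plot a within-case evolvability-divergence regression
#'
#' Scatter of log divergence against log (conditional) evolvability over the
#' direction set, with the fitted OLS line and a dashed 1:1 (isometry) line
#' through the data centroid.
#'
#' @param x a `case_slope` from [case_regression()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.case_slope <- function(x, ...) {
  ok <- x$e > 0 & x$d > 0
  lx <- log(x$e[ok]); ly <- log(x$d[ok])
  graphics::plot(lx, ly,
                 xlab = if (x$conditional) "log c(v)" else "log e(v)",
                 ylab = "log d(v)",
                 main = sprintf("Case %s (%s): slope %.2f, r2 %.2f",
                                x$case_id, x$direction_set, x$slope, x$r2),
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  graphics::abline(mean(ly) - mean(lx), 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Plot the univariate evolvability-divergence relationship
#'
#' Scatter of log divergence on log evolvability (point area proportional
#' to the number of populations behind each divergence estimate), with the
#' raw and attenuation-corrected fitted slopes drawn through the centroid.
#'
#' @param x a `univariate_fit` from [run_univariate()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.univariate_fit <- function(x, ...) {
  ds <- x$dataset
  graphics::plot(ds$log_e, ds$log_d, cex = sqrt(ds$n_pop) / 2,
                 xlab = "log evolvability", ylab = "log divergence",
                 pch = 21, bg = "grey80", ...)
  cx <- mean(ds$log_e); cy <- mean(ds$log_d)
  graphics::abline(cy - x$raw_slope * cx, x$raw_slope)
  graphics::abline(cy - x$corrected$corrected * cx, x$corrected$corrected,
                   lty = 2)
  graphics::legend("topleft", lty = c(1, 2), bty = "n",
                   legend = c(sprintf("raw slope %.2f", x$raw_slope),
                              sprintf("corrected %.2f",
                                      x$corrected$corrected)))
  invisible(x)
}
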