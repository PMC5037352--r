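#' Power-law fit y = m * x^b
#'
#' Ordinary least squares of `log(y)` on `log(x)`; the slope is the exponent
#' `b` and the intercept back-transforms to the prefactor `m`. `r_squared`
#' and the two-sided p-value for `b` (t distribution, n - 2 df) are reported
#' on the log scale, where multiplicative lognormal noise is exactly the
#' model's error term. The base of logarithms is immaterial to `b` and
#' `r_squared`; natural logs are used and `m = exp(intercept)`.
#'
#' @param x,y positive numeric vectors, length >= 3
#' @return a `regression_fit` list: `model, m, b, r_squared, n, p_value`
#' @export
fit_power <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs")
  if (any(x <= 0) || any(y <= 0)) stop("power fit requires positive x and y")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  fit <- stats::lm(log(y) ~ log(x))
  sm <- summary(fit)
  structure(list(model = "power",
                 m = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 n = length(x),
                 p_value = unname(sm$coefficients[2, 4]),
                 lm = fit),
            class = "regression_fit")
}

#' Ordinary least-squares linear fit y = m + b * x
#'
#' @param x,y numeric vectors, length >= 3
#' @return a `regression_fit` list: `model, m` (intercept), `b` (slope),
#'   `r_squared, n, p_value`
#' @export
fit_linear <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(model = "linear",
                 m = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 n = length(x),
                 p_value = unname(sm$coefficients[2, 4]),
                 lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  eq <- if (x$model == "power") {
    sprintf("y = %.4g * x^%.4g", x$m, x$b)
  } else {
    sprintf("y = %.4g + %.4g * x", x$m, x$b)
  }
  cat("<regression_fit> ", x$model, ": ", eq,
      sprintf("  (R^2 = %.3f, n = %d, p = %.3g)\n", x$r_squared, x$n,
              x$p_value), sep = "")
  invisible(x)
}

#' Flag residual outliers of a fitted trend
#'
#' Marks points whose residual (on the fit's own scale: log for power fits)
#' exceeds `k_sd` residual standard deviations in magnitude, the convention
#' used to separate a main data series from gross outliers.
#'
#' @param fit a `regression_fit`
#' @param x,y the data to flag (defaults: the data the fit was made on)
#' @param k_sd flag threshold in residual standard deviations (default 2.5)
#' @return logical vector, `TRUE` for flagged points
#' @export
outlier_flags <- function(fit, x = NULL, y = NULL, k_sd = 2.5) {
  stopifnot(inherits(fit, "regression_fit"), k_sd > 0)
  if (is.null(x) || is.null(y)) {
    res <- stats::residuals(fit$lm)
  } else {
    if (fit$model == "power") {
      res <- log(y) - (log(fit$m) + fit$b * log(x))
    } else {
      res <- y - (fit$m + fit$b * x)
    }
  }
  if (!is.finite(k_sd)) return(rep(FALSE, length(res)))
  s <- stats::sd(res)
  # an essentially perfect fit has no outliers: guard against sd at the
  # level of floating-point noise relative to the response scale
  resp <- stats::model.frame(fit$lm)[[1]]
  if (s <= 1e-8 * max(stats::sd(resp), 1)) return(rep(FALSE, length(res)))
  abs(res) > k_sd * s
}
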