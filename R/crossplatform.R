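# Quadratic least-squares adjustment between expression scales of two
# scRNA-seq platforms. The curve is fitted on paired pseudo-bulk log
# expression of the same nominal cell type profiled on both platforms,
# then applied to the whole comparison dataset.

#' Construct a quadratic calibration from known coefficients
#'
#' `y = a*x^2 + b*x + c`. Useful for applying a previously fitted or
#' published adjustment curve directly.
#'
#' @param a,b,c finite real coefficients.
#' @param n_points number of points behind the fit, if known.
#' @param rss residual sum of squares of the fit, if known.
#' @return A `PolyFit` object.
#' @export
poly_fit <- function(a, b, c, n_points = NA_integer_, rss = NA_real_) {
  if (!all(is.finite(c(a, b, c))))
    config_error("polynomial coefficients must be finite")
  structure(list(a = a, b = b, c = c, n_points = n_points, rss = rss),
            class = "PolyFit")
}

#' Fit a quadratic calibration curve by ordinary least squares
#'
#' Regresses `y` on the monomial basis `{x^2, x, 1}`, minimizing the
#' residual sum of squares. Inputs are typically per-feature pseudo-bulk
#' mean log2 expression of the same cell type on the two platforms, paired
#' by shared feature identifier.
#'
#' @param x,y equal-length numeric vectors, `length >= 3`, with at least 3
#'   distinct `x` values.
#' @return A `PolyFit` with coefficients `a`, `b`, `c`, `n_points` and
#'   `rss`.
#' @export
fit_quadratic <- function(x, y) {
  if (length(x) != length(y)) input_error("x and y must have equal length")
  if (length(x) < 3 || length(unique(x)) < 3)
    scte_error("need >= 3 points with >= 3 distinct x for a unique quadratic",
               "scte_rank_error")
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  if (anyNA(cf)) scte_error("degenerate design: quadratic fit is rank deficient",
                            "scte_rank_error")
  poly_fit(a = unname(cf["I(x^2)"]), b = unname(cf["x"]),
           c = unname(cf["(Intercept)"]),
           n_points = length(x), rss = sum(fit$residuals^2))
}

#' Apply a quadratic adjustment element-wise
#'
#' Evaluates `a*x^2 + b*x + c` for every value; no clamping is applied, so
#' values outside the fitted range extrapolate along the curve.
#'
#' @param fit a `PolyFit`.
#' @param values finite numeric vector (or matrix) on the source scale.
#' @return Adjusted values, same shape and names as `values`.
#' @export
apply_adjustment <- function(fit, values) {
  if (!inherits(fit, "PolyFit")) input_error("fit must be a PolyFit")
  fit$a * values^2 + fit$b * values + fit$c
}

#' @export
print.PolyFit <- function(x, ...) {
  cat(sprintf("PolyFit: y = %.4g*x^2 + %.4g*x + %.4g", x$a, x$b, x$c))
  if (!is.na(x$n_points))
    cat(sprintf("  (n = %d, RSS = %.4g)", x$n_points, x$rss))
  cat("\n")
  invisible(x)
}
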