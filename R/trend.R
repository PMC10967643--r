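#' Fit a straight-line trend by ordinary least squares
#'
#' Workhorse for the degradation trends: Lioumbas `b` versus processing time,
#' `a` versus `b`, and TPC versus processing time. The coefficient of
#' determination is computed on the original scale; when the response has
#' zero residual spread, `r2` is defined as 1.
#'
#' @param x,y Numeric vectors of equal length `>= 3`; `x` must not be
#'   constant.
#' @param xlab,ylab Optional axis labels stored with the fit.
#' @return Object of class `trend_fit` with elements `slope`, `intercept`,
#'   `r2`, `n`, and the fitted range of `x`.
#' @examples
#' fit_linear_trend(c(0, 8, 16, 24, 32), c(7, 11, 18.5, 23, 35.5))
#' @export
fit_linear_trend <- function(x, y, xlab = "x", ylab = "y") {
  if (length(x) != length(y)) {
    stop_validation("x and y differ in length")
  }
  if (length(x) < 3L) {
    stop_validation("at least 3 points are required for a trend fit (got %d)",
                    length(x))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("trend data contain non-finite values")
  }
  f <- ols_r2(x, y)
  structure(list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
                 n = length(x), x_range = range(x),
                 xlab = xlab, ylab = ylab),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear trend: %s = %.*g * %s %+.*g  (R^2 = %.3f, n = %d)\n",
              x$ylab, digits, x$slope, x$xlab, digits, x$intercept,
              x$r2, x$n))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Evaluate a trend fit
#'
#' @param object A `trend_fit`.
#' @param x Points at which to evaluate the line.
#' @param ... Unused.
#' @return Fitted values `intercept + slope * x`.
#' @export
predict.trend_fit <- function(object, x, ...) {
  object$intercept + object$slope * x
}

#' Fit the TPC-versus-time trend for one treatment
#'
#' Total polar compounds accumulate approximately linearly with heating time
#' at frying temperature; the fitted line is the basis for waste-point
#' prediction.
#'
#' @param series A TPC series (data frame with columns `t_P_h`,
#'   `tpc_percent`; see [read_tpc_table()]).
#' @return A [fit_linear_trend()] object of TPC (%) on time (h).
#' @export
fit_tpc_trend <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("t_P_h", "tpc_percent") %in% names(series))) {
    stop_validation("expected a TPC series with columns t_P_h and tpc_percent")
  }
  fit_linear_trend(series$t_P_h, series$tpc_percent,
                   xlab = "t_P [h]", ylab = "TPC [%]")
}

#' Regulatory waste point from a fitted TPC trend
#'
#' The processing time at which the fitted TPC line crosses the disposal
#' threshold (27% under the Chinese standard; 24-27% in most jurisdictions):
#' `(threshold - intercept) / slope`.
#'
#' @param trend A `trend_fit` of TPC on time with positive slope.
#' @param threshold TPC threshold in percent (default 27).
#' @return Hours to the threshold crossing, with attribute
#'   `already_exceeded = TRUE` (and a value `<= 0`) when the intercept is at
#'   or above the threshold.
#' @examples
#' tr <- fit_linear_trend(c(0, 8, 16, 24, 32), c(7, 11, 18.5, 23, 35.5))
#' waste_point(tr) # about 25.3 h
#' @export
waste_point <- function(trend, threshold = 27) {
  stopifnot(inherits(trend, "trend_fit"))
  if (trend$slope <= 0) {
    stop_domain("TPC trend slope is not positive; the threshold is never crossed")
  }
  t_cross <- (threshold - trend$intercept) / trend$slope
  if (trend$intercept >= threshold) {
    attr(t_cross, "already_exceeded") <- TRUE
  }
  t_cross
}
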