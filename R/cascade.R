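#' Build a degradation cascade from per-timepoint Lioumbas fits
#'
#' The cascade chains two linear trends observed during thermal degradation:
#' the Lioumbas curvature coefficient `b` drifts linearly with processing
#' time, and the intercept `a` is linear in `b` (slopes around -42 for
#' rapeseed oil). Composed with the Lioumbas law itself this yields a
#' forward model for viscosity at any processing time and temperature:
#' \deqn{b(t_P) \rightarrow a(b) \rightarrow
#'       \mu = \exp(a + b (\ln T_m)^2).}
#'
#' @param params Either a data frame with columns `t_P`, `a`, `b` (one row
#'   per processing time) or a list of [fit_lioumbas()] objects each carrying
#'   a `t_P`.
#' @param treatment Optional treatment label.
#' @return Object of class `cascade_model` with elements `b_trend`,
#'   `a_of_b` (both [fit_linear_trend()] objects) and `t_P_range`.
#' @seealso [oil_cascade()] to fit directly from sweeps,
#'   [predict.cascade_model()]
#' @export
build_cascade <- function(params, treatment = NULL) {
  if (is.list(params) && !is.data.frame(params) &&
      all(vapply(params, inherits, logical(1), "lioumbas_fit"))) {
    params <- data.frame(t_P = vapply(params, function(f) f$t_P %||% NA_real_,
                                      numeric(1)),
                         a = vapply(params, function(f) f$a, numeric(1)),
                         b = vapply(params, function(f) f$b, numeric(1)))
  }
  if (!is.data.frame(params) || !all(c("t_P", "a", "b") %in% names(params))) {
    stop_validation("params must be a data frame with columns t_P, a, b or a list of lioumbas_fit objects with t_P")
  }
  if (nrow(params) < 3L) {
    stop_validation("at least 3 processing times are required to build a cascade (got %d)",
                    nrow(params))
  }
  if (anyDuplicated(params$t_P)) {
    stop_validation("duplicate processing times in cascade input")
  }
  b_trend <- fit_linear_trend(params$t_P, params$b, xlab = "t_P [h]", ylab = "b")
  a_of_b <- fit_linear_trend(params$b, params$a, xlab = "b", ylab = "a")
  structure(list(b_trend = b_trend, a_of_b = a_of_b,
                 t_P_range = range(params$t_P), params = params,
                 treatment = treatment),
            class = "cascade_model")
}

#' Fit the full viscosity degradation cascade from sweeps
#'
#' The one-call interface: fits the Lioumbas model to each sweep, then chains
#' the fitted parameters over processing time with [build_cascade()]. All
#' sweeps should belong to one treatment.
#'
#' @param sweeps List of viscosity sweeps at distinct processing times (at
#'   least 3), as from [read_viscosity_sweeps()] or [generate_study()].
#' @return A `cascade_model` whose `fits` element keeps the per-timepoint
#'   Lioumbas fits.
#' @examples
#' Tg <- seq(60, 110, 5)
#' sweeps <- lapply(c(0, 8, 16, 24, 32), function(tp) {
#'   b <- -0.0006 * tp - 0.1964
#'   a <- -42.57 * b - 2.04
#'   viscosity_sweep(Tg, exp(a + b * log(Tg)^2), t_P = tp)
#' })
#' cm <- oil_cascade(sweeps)
#' predict(cm, t_P = 16, temperature_C = 60)
#' @export
oil_cascade <- function(sweeps) {
  fits <- lapply(sweeps, fit_lioumbas)
  t_P <- vapply(sweeps, function(s) attr(s, "t_P") %||% NA_real_, numeric(1))
  if (any(is.na(t_P))) {
    stop_validation("every sweep needs a t_P attribute (processing time in hours)")
  }
  params <- data.frame(t_P = t_P,
                       a = vapply(fits, function(f) f$a, numeric(1)),
                       b = vapply(fits, function(f) f$b, numeric(1)))
  treatments <- unique(vapply(sweeps, function(s) {
    attr(s, "treatment") %||% NA_character_
  }, character(1)))
  cm <- build_cascade(params,
                      treatment = if (length(treatments) == 1L) treatments else NULL)
  cm$fits <- fits
  cm
}

#' Predict viscosity from a degradation cascade
#'
#' Evaluates `b = b_trend(t_P)`, `a = a_of_b(b)` and
#' `mu = exp(a + b (ln T)^2)`. Predictions at processing times outside the
#' fitted range are returned but flagged with a warning and an
#' `extrapolated` attribute.
#'
#' @param object A `cascade_model`.
#' @param t_P Processing time(s) in hours.
#' @param temperature_C Temperature(s) in degrees Celsius, `> 0`. Recycled
#'   against `t_P`.
#' @param ... Unused.
#' @return Viscosity in mPa s, with attribute `extrapolated` (logical per
#'   element).
#' @export
predict.cascade_model <- function(object, t_P, temperature_C, ...) {
  if (any(!is.finite(temperature_C)) || any(temperature_C <= 0)) {
    stop_domain("temperature must be positive (degrees Celsius)")
  }
  n <- max(length(t_P), length(temperature_C))
  t_P <- rep_len(t_P, n)
  temperature_C <- rep_len(temperature_C, n)
  b <- predict(object$b_trend, t_P)
  a <- predict(object$a_of_b, b)
  mu <- exp(a + b * log(temperature_C)^2)
  extrap <- t_P < object$t_P_range[1L] | t_P > object$t_P_range[2L]
  if (any(extrap)) {
    warning(sprintf("extrapolating beyond the fitted processing-time range [%g, %g] h",
                    object$t_P_range[1L], object$t_P_range[2L]))
  }
  attr(mu, "extrapolated") <- extrap
  mu
}

#' @export
print.cascade_model <- function(x, digits = 4, ...) {
  cat("Viscosity degradation cascade",
      if (!is.null(x$treatment)) sprintf("(treatment %s)", x$treatment), "\n")
  cat(sprintf("  b(t_P) = %.*g t_P %+.*g   (R^2 = %.3f)\n",
              digits, x$b_trend$slope, digits, x$b_trend$intercept,
              x$b_trend$r2))
  cat(sprintf("  a(b)   = %.*g b %+.*g   (R^2 = %.3f)\n",
              digits, x$a_of_b$slope, digits, x$a_of_b$intercept,
              x$a_of_b$r2))
  cat(sprintf("  fitted over t_P in [%g, %g] h; mu = exp(a + b (ln T_C)^2)\n",
              x$t_P_range[1L], x$t_P_range[2L]))
  invisible(x)
}

#' @export
coef.cascade_model <- function(object, ...) {
  c(b_slope = object$b_trend$slope, b_intercept = object$b_trend$intercept,
    a_slope = object$a_of_b$slope, a_intercept = object$a_of_b$intercept)
}

#' @export
summary.cascade_model <- function(object, ...) {
  structure(list(model = object,
                 param_table = object$params,
                 b_r2 = object$b_trend$r2, a_r2 = object$a_of_b$r2),
            class = "summary.cascade_model")
}

#' @export
print.summary.cascade_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-timepoint Lioumbas parameters:\n")
  print(x$param_table, row.names = FALSE)
  invisible(x)
}

#' Parity plot of a cascade against observed viscosities
#'
#' Observed versus cascade-calculated viscosity with the identity line;
#' the conventional visual check of forward-model accuracy.
#'
#' @param x A `cascade_model` with per-timepoint fits (from [oil_cascade()]).
#' @param sweeps The sweeps the model was fitted to.
#' @param ... Passed to [graphics::plot()].
#' @return The parity data frame, invisibly.
#' @export
plot.cascade_model <- function(x, sweeps, ...) {
  obs <- unlist(lapply(sweeps, function(s) s$viscosity_mPa_s))
  calc <- unlist(lapply(sweeps, function(s) {
    suppressWarnings(predict(x, t_P = attr(s, "t_P"),
                             temperature_C = s$temperature_C))
  }))
  graphics::plot(obs, calc, xlab = "observed viscosity [mPa s]",
                 ylab = "calculated viscosity [mPa s]", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(data.frame(observed = obs, calculated = calc))
}

#' Parity (observed versus calculated) analysis
#'
#' Per-pair residuals and percent deviations, normalised by the observed
#' value, plus the summary extrema used to state model accuracy bounds
#' (e.g. "within +/-2 mPa s and +/-10%").
#'
#' @param observed,calculated Numeric vectors of equal length; `observed`
#'   must not contain zeros (the deviation is undefined there).
#' @return Object of class `parity_analysis`: a data frame with columns
#'   `observed`, `calculated`, `residual`, `deviation_pct` and attributes
#'   `max_abs_residual`, `max_abs_deviation_pct`.
#' @examples
#' parity_analysis(c(10, 20), c(9, 22))
#' @export
parity_analysis <- function(observed, calculated) {
  if (length(observed) != length(calculated)) {
    stop_validation("observed and calculated differ in length")
  }
  zero <- which(observed == 0)
  if (length(zero) > 0L) {
    stop_domain("observed value is zero at pair %d; deviation%% undefined",
                zero[1L])
  }
  residual <- observed - calculated
  deviation_pct <- residual / observed * 100
  structure(data.frame(observed = observed, calculated = calculated,
                       residual = residual, deviation_pct = deviation_pct),
            max_abs_residual = max(abs(residual)),
            max_abs_deviation_pct = max(abs(deviation_pct)),
            class = c("parity_analysis", "data.frame"))
}

#' @export
print.parity_analysis <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("max |residual| = %.4g, max |deviation| = %.4g %%\n",
              attr(x, "max_abs_residual"), attr(x, "max_abs_deviation_pct")))
  invisible(x)
}

#' Regress the Lioumbas curvature on oil composition
#'
#' Fits the two-predictor plane `b = intercept + coef_ecn * ECN +
#' coef_tpc * TPC` over pooled (treatment x time) observations, linking the
#' viscosity-temperature behaviour to the chemical state of the oil.
#'
#' @param b Lioumbas `b` values.
#' @param ecn Effective carbon numbers.
#' @param tpc Total polar compounds in percent.
#' @return Object of class `plane_fit` with `intercept`, `coef_ecn`,
#'   `coef_tpc`, `r2`, `n`.
#' @export
fit_b_on_composition <- function(b, ecn, tpc) {
  if (length(b) != length(ecn) || length(b) != length(tpc)) {
    stop_validation("b, ecn and tpc differ in length")
  }
  if (length(b) < 4L) {
    stop_validation("at least 4 observations are required (got %d)", length(b))
  }
  X <- cbind(1, ecn, tpc)
  if (qr(X)$rank < 3L) {
    stop_singular("singular design: ECN and TPC columns are collinear or constant")
  }
  fit <- stats::lm.fit(X, b)
  ssres <- sum(fit$residuals^2)
  sstot <- sum((b - mean(b))^2)
  r2 <- if (sstot <= .Machine$double.eps * max(1, sum(b^2))) 1 else 1 - ssres / sstot
  cf <- unname(fit$coefficients)
  structure(list(intercept = cf[1L], coef_ecn = cf[2L], coef_tpc = cf[3L],
                 r2 = r2, n = length(b)),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Composition plane: b = %.*g %+.*g ECN %+.*g TPC  (R^2 = %.3f, n = %d)\n",
              digits, x$intercept, digits, x$coef_ecn, digits, x$coef_tpc,
              x$r2, x$n))
  invisible(x)
}

#' @export
coef.plane_fit <- function(object, ...) {
  c(intercept = object$intercept, coef_ecn = object$coef_ecn,
    coef_tpc = object$coef_tpc)
}
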