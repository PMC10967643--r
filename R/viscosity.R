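#' Construct a viscosity sweep
#'
#' One sample at one processing time: viscosity versus temperature at a fixed
#' shear rate. Points are sorted by temperature.
#'
#' @param temperature_C Temperatures in degrees Celsius, all `> 0`.
#' @param viscosity_mPa_s Dynamic viscosities in mPa s, all `> 0`.
#' @param sample_id,treatment Identifying labels.
#' @param t_P Processing time in hours.
#' @param shear_rate Shear rate metadata in 1/s (the oils are Newtonian, so
#'   viscosity does not depend on it; it is carried for provenance).
#' @return An object of class `viscosity_sweep`.
#' @export
viscosity_sweep <- function(temperature_C, viscosity_mPa_s,
                            sample_id = "sample", treatment = "C",
                            t_P = 0, shear_rate = 50) {
  if (length(temperature_C) != length(viscosity_mPa_s)) {
    stop_validation("temperature and viscosity vectors differ in length")
  }
  if (any(!is.finite(temperature_C)) || any(temperature_C <= 0)) {
    stop_validation("all temperatures must be positive (degrees Celsius)")
  }
  if (any(!is.finite(viscosity_mPa_s)) || any(viscosity_mPa_s <= 0)) {
    stop_validation("all viscosities must be positive")
  }
  o <- order(temperature_C)
  if (anyDuplicated(temperature_C)) {
    stop_validation("duplicate temperatures in sweep '%s'", sample_id)
  }
  structure(data.frame(temperature_C = temperature_C[o],
                       viscosity_mPa_s = viscosity_mPa_s[o]),
            sample_id = sample_id, treatment = treatment, t_P = t_P,
            shear_rate = shear_rate,
            class = c("viscosity_sweep", "data.frame"))
}

check_sweep <- function(sweep) {
  if (!is.data.frame(sweep) ||
      !all(c("temperature_C", "viscosity_mPa_s") %in% names(sweep))) {
    stop_validation("expected a viscosity sweep with columns temperature_C and viscosity_mPa_s")
  }
  if (nrow(sweep) < 3L) {
    stop_validation("at least 3 points are required to fit a sweep (got %d)",
                    nrow(sweep))
  }
  if (any(sweep$viscosity_mPa_s <= 0) || any(sweep$temperature_C <= 0)) {
    stop_validation("sweep contains non-positive viscosity or temperature")
  }
  invisible(sweep)
}

# OLS of y on a single regressor with the degenerate-variance conventions
# used throughout: zero residual spread => r2 = 1.
ols_r2 <- function(x, y) {
  if (stats::var(x) == 0) {
    stop_singular("singular design: regressor is constant")
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  ssres <- sum(fit$residuals^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot <= .Machine$double.eps * max(1, sum(y^2))) {
    1
  } else {
    1 - ssres / sstot
  }
  list(intercept = unname(fit$coefficients[1L]),
       slope = unname(fit$coefficients[2L]),
       r2 = r2, residuals = unname(fit$residuals),
       fitted = unname(y - fit$residuals))
}

#' Fit the Lioumbas viscosity-temperature model
#'
#' The empirical law \deqn{\ln \mu = a + b (\ln T_m)^2} with temperature in
#' degrees Celsius. Fitted by ordinary least squares of \eqn{\ln \mu} on
#' \eqn{(\ln T_m)^2}; the goodness of fit `r2` is reported on the log scale
#' the regression is computed on. `b` is negative for liquids that thin with
#' temperature; `a` sets the viscosity scale.
#'
#' Temperature enters in Celsius: with typical fitted parameters for
#' vegetable oils (a around 6.3, b around -0.19) the Celsius form predicts
#' 20-30 mPa s at 60 degrees C, the observed magnitude, whereas a Kelvin form
#' would predict well under 1 mPa s.
#'
#' @param sweep A [viscosity_sweep()] (or data frame with columns
#'   `temperature_C`, `viscosity_mPa_s`), at least 3 points.
#' @return Object of class `lioumbas_fit` with elements `a`, `b`, `r2`,
#'   `n_points`, plus residuals/fitted values on the log scale.
#' @examples
#' T <- seq(60, 110, 5)
#' sw <- viscosity_sweep(T, exp(6.32 - 0.19 * log(T)^2))
#' fit_lioumbas(sw)
#' @seealso [fit_arrhenius()], [predict.lioumbas_fit()], [compare_models()]
#' @export
fit_lioumbas <- function(sweep) {
  check_sweep(sweep)
  x <- log(sweep$temperature_C)^2
  y <- log(sweep$viscosity_mPa_s)
  f <- ols_r2(x, y)
  structure(list(a = f$intercept, b = f$slope, r2 = f$r2,
                 n_points = nrow(sweep),
                 residuals = f$residuals, fitted_log = f$fitted,
                 temperature_C = sweep$temperature_C,
                 sample_id = attr(sweep, "sample_id"),
                 t_P = attr(sweep, "t_P")),
            class = "lioumbas_fit")
}

#' Fit the Arrhenius viscosity-temperature model
#'
#' \deqn{\ln \mu = \ln \mu_0 + E_a / (R \, T_K)} with \eqn{T_K = T_m + 273.15}
#' and the gas constant \eqn{R = 8.314} J/(mol K). Fitted by OLS of
#' \eqn{\ln \mu} on \eqn{1/(R T_K)}; the slope is the flow activation energy
#' `Ea` (J/mol), `exp(intercept)` the pre-exponential viscosity `mu0`.
#'
#' @inheritParams fit_lioumbas
#' @return Object of class `arrhenius_fit` with elements `mu0`, `Ea`, `r2`,
#'   `gas_constant`, `n_points`.
#' @examples
#' T <- seq(60, 110, 5)
#' sw <- viscosity_sweep(T, 0.04 * exp(16684.93 / (8.314 * (T + 273.15))))
#' fit_arrhenius(sw)
#' @export
fit_arrhenius <- function(sweep) {
  check_sweep(sweep)
  R <- 8.314
  x <- 1 / (R * (sweep$temperature_C + 273.15))
  y <- log(sweep$viscosity_mPa_s)
  f <- ols_r2(x, y)
  structure(list(mu0 = exp(f$intercept), Ea = f$slope, r2 = f$r2,
                 gas_constant = R, n_points = nrow(sweep),
                 residuals = f$residuals, fitted_log = f$fitted,
                 temperature_C = sweep$temperature_C,
                 sample_id = attr(sweep, "sample_id"),
                 t_P = attr(sweep, "t_P")),
            class = "arrhenius_fit")
}

#' @export
print.lioumbas_fit <- function(x, digits = 4, ...) {
  cat("Lioumbas viscosity-temperature fit: ln(mu) = a + b (ln T_C)^2\n")
  cat(sprintf("  a = %.*g, b = %.*g  (R^2 = %.4f on ln scale, n = %d)\n",
              digits, x$a, digits, x$b, x$r2, x$n_points))
  invisible(x)
}

#' @export
print.arrhenius_fit <- function(x, digits = 4, ...) {
  cat("Arrhenius viscosity-temperature fit: ln(mu) = ln(mu0) + Ea/(R T_K)\n")
  cat(sprintf("  mu0 = %.*g mPa s, Ea = %.*g J/mol  (R^2 = %.4f, n = %d)\n",
              digits, x$mu0, digits, x$Ea, x$r2, x$n_points))
  invisible(x)
}

#' @export
coef.lioumbas_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
coef.arrhenius_fit <- function(object, ...) c(mu0 = object$mu0, Ea = object$Ea)

#' @export
residuals.lioumbas_fit <- function(object, ...) object$residuals

#' @export
residuals.arrhenius_fit <- function(object, ...) object$residuals

#' Predict viscosity from a Lioumbas fit
#'
#' @param object A `lioumbas_fit`.
#' @param temperature_C Temperatures in degrees Celsius, all `> 0`.
#' @param ... Unused.
#' @return Predicted viscosities in mPa s.
#' @export
predict.lioumbas_fit <- function(object, temperature_C, ...) {
  predict_lioumbas_ab(object$a, object$b, temperature_C)
}

predict_lioumbas_ab <- function(a, b, temperature_C) {
  if (any(!is.finite(temperature_C)) || any(temperature_C <= 0)) {
    stop_domain("temperature must be positive (degrees Celsius)")
  }
  exp(a + b * log(temperature_C)^2)
}

#' Predict viscosity from an Arrhenius fit
#'
#' @param object An `arrhenius_fit`.
#' @param temperature_C Temperatures in degrees Celsius, `> -273.15`.
#' @param ... Unused.
#' @return Predicted viscosities in mPa s.
#' @export
predict.arrhenius_fit <- function(object, temperature_C, ...) {
  if (any(!is.finite(temperature_C)) || any(temperature_C <= -273.15)) {
    stop_domain("temperature must exceed absolute zero")
  }
  object$mu0 * exp(object$Ea / (object$gas_constant * (temperature_C + 273.15)))
}

#' Compare the two viscosity-temperature models on one sweep
#'
#' Fits both the Lioumbas and the Arrhenius model and reports which attains
#' the higher coefficient of determination on the log-viscosity scale. Ties
#' go to the Lioumbas model, the simpler empirical description for vegetable
#' oils over 60-110 degrees C.
#'
#' @inheritParams fit_lioumbas
#' @return A list of class `model_comparison`: `lioumbas`, `arrhenius`,
#'   `delta_r2` (Lioumbas minus Arrhenius) and `winner`.
#' @export
compare_models <- function(sweep) {
  lio <- fit_lioumbas(sweep)
  arr <- fit_arrhenius(sweep)
  delta <- lio$r2 - arr$r2
  structure(list(lioumbas = lio, arrhenius = arr, delta_r2 = delta,
                 winner = if (delta >= 0) "lioumbas" else "arrhenius"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison: Lioumbas R^2 = %.4f vs Arrhenius R^2 = %.4f\n",
              x$lioumbas$r2, x$arrhenius$r2))
  cat(sprintf("  preferred model: %s (delta R^2 = %+.4f)\n", x$winner, x$delta_r2))
  invisible(x)
}

#' Fit both models across a set of sweeps
#'
#' Produces the standard per-condition parameter table: one row per sweep
#' with both models' coefficients and goodness of fit.
#'
#' @param sweeps List of sweeps (see [read_viscosity_sweeps()]).
#' @return Data frame with columns `sample_id`, `treatment`, `t_P_h`, `a`,
#'   `b`, `r2_lioumbas`, `mu0`, `Ea`, `r2_arrhenius`.
#' @export
fit_sweep_table <- function(sweeps) {
  do.call(rbind, lapply(sweeps, function(s) {
    lio <- fit_lioumbas(s)
    arr <- fit_arrhenius(s)
    data.frame(sample_id = attr(s, "sample_id") %||% NA_character_,
               treatment = attr(s, "treatment") %||% NA_character_,
               t_P_h = attr(s, "t_P") %||% NA_real_,
               a = lio$a, b = lio$b, r2_lioumbas = lio$r2,
               mu0 = arr$mu0, Ea = arr$Ea, r2_arrhenius = arr$r2,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
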