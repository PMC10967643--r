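#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations across the study variables (model
#' parameters, ECN, TPC, processing time, viscosities), with two-sided
#' p-values from the t-distribution on `n - 2` degrees of freedom and the
#' conventional significance flags (`*` at 0.05, `**` at 0.01). No
#' multiple-testing correction is applied. A zero-variance variable gets its
#' row and column set to `NA` with a named warning rather than propagating
#' silent `NaN`s.
#'
#' @param table A data frame (or named list) of aligned numeric vectors, one
#'   per variable, each of length `n >= 3`, no missing values.
#' @return Object of class `correlation_result` with elements `variables`,
#'   `r`, `p` (square matrices), `flags` (character matrix of `""`, `"*"`,
#'   `"**"`) and `n`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = 1:10, y = 1:10 + rnorm(10))
#' pearson_matrix(d)
#' @export
pearson_matrix <- function(table) {
  table <- as.data.frame(table)
  if (ncol(table) < 2L) {
    stop_validation("need at least two variables")
  }
  if (anyNA(table)) {
    stop_validation("missing values are not allowed")
  }
  n <- nrow(table)
  if (n < 3L) {
    stop_validation("need at least 3 aligned observations (got %d)", n)
  }
  vars <- names(table)
  degenerate <- vapply(table, function(v) stats::var(v) == 0, logical(1))
  if (any(degenerate)) {
    warning(sprintf("zero-variance variable(s): %s; correlations set to NA",
                    paste(vars[degenerate], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(table, method = "pearson"))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- ifelse(degenerate, NA_real_, 1)
  # two-sided p from t = r sqrt((n-2)/(1-r^2)); r = +/-1 exactly => p = 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.infinite(tstat)] <- 0
  p[abs(r) >= 1] <- 0
  diag(p) <- ifelse(degenerate, NA_real_, 0)
  flags <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.01] <- "**"
  diag(flags) <- ""
  structure(list(variables = vars, r = r, p = p, flags = flags, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation over %d observations (one per treatment x time condition)\n",
              x$n))
  shown <- matrix(sprintf("%.*f%s", digits, x$r, x$flags),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[is.na(x$r)] <- "NA"
  print(shown, quote = FALSE)
  cat("*: p < 0.05, **: p < 0.01 (two-sided, uncorrected)\n")
  invisible(x)
}

#' Assemble the study-variable table for correlation analysis
#'
#' Joins per-condition Lioumbas/Arrhenius parameters, ECN, TPC, processing
#' time and viscosities at reference temperatures into one observation table,
#' one row per (treatment, t_P) condition, for [pearson_matrix()].
#'
#' @param param_table Output of [fit_sweep_table()].
#' @param composition Output of [composition_summary()].
#' @param tpc List of TPC series (see [read_tpc_table()]).
#' @param ref_temps Temperatures (degrees C) at which Lioumbas-predicted
#'   viscosities are added as variables (default 60 and 100).
#' @return Data frame with one row per condition present in all three inputs.
#' @export
study_variable_table <- function(param_table, composition, tpc,
                                 ref_temps = c(60, 100)) {
  tpc_df <- do.call(rbind, lapply(tpc, function(s) {
    data.frame(treatment = attr(s, "treatment"), t_P_h = s$t_P_h,
               TPC = s$tpc_percent, stringsAsFactors = FALSE)
  }))
  comp <- composition[, c("treatment", "t_P_h", "ecn")]
  names(comp)[3L] <- "ECN"
  out <- merge(merge(param_table, comp, by = c("treatment", "t_P_h")),
               tpc_df, by = c("treatment", "t_P_h"))
  for (Tm in ref_temps) {
    out[[sprintf("viscosity_%gC", Tm)]] <-
      exp(out$a + out$b * log(Tm)^2)
  }
  out
}
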