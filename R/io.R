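# CSV readers and writers for the three study tables. All files are plain
# comma-separated UTF-8 with a single header row and "." decimals.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_format("%s: missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
}

#' Read viscosity sweeps from CSV
#'
#' A sweep is one sample at one processing time: viscosity measured over a
#' rising temperature ramp at a fixed shear rate. Rows are grouped by
#' `(sample_id, t_P_h)` and each sweep's points are sorted by temperature,
#' so reader output does not depend on input row order.
#'
#' @param path CSV file with header
#'   `sample_id,treatment,t_P_h,shear_rate_per_s,temperature_C,viscosity_mPa_s`.
#' @return A list of sweeps. Each sweep is a data frame with columns
#'   `temperature_C`, `viscosity_mPa_s` and attributes `sample_id`,
#'   `treatment`, `t_P`, `shear_rate`.
#' @seealso [write_viscosity_sweeps()], [fit_lioumbas()]
#' @export
read_viscosity_sweeps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "treatment", "t_P_h", "shear_rate_per_s",
                      "temperature_C", "viscosity_mPa_s"),
                "viscosity sweep file")
  bad_mu <- which(!is.finite(df$viscosity_mPa_s) | df$viscosity_mPa_s <= 0)
  if (length(bad_mu) > 0L) {
    stop_validation("non-positive viscosity at data row %d", bad_mu[1L])
  }
  bad_T <- which(!is.finite(df$temperature_C) | df$temperature_C <= 0)
  if (length(bad_T) > 0L) {
    stop_validation("non-positive temperature at data row %d", bad_T[1L])
  }
  key <- interaction(df$sample_id, df$t_P_h, drop = TRUE, lex.order = TRUE)
  sweeps <- lapply(split(df, key), function(g) {
    g <- g[order(g$temperature_C), , drop = FALSE]
    if (anyDuplicated(g$temperature_C)) {
      stop_validation("duplicate temperature in sweep '%s' at t_P = %g h",
                      g$sample_id[1L], g$t_P_h[1L])
    }
    structure(data.frame(temperature_C = g$temperature_C,
                         viscosity_mPa_s = g$viscosity_mPa_s),
              sample_id = g$sample_id[1L], treatment = g$treatment[1L],
              t_P = g$t_P_h[1L], shear_rate = g$shear_rate_per_s[1L],
              class = c("viscosity_sweep", "data.frame"))
  })
  names(sweeps) <- NULL
  sweeps
}

#' Write viscosity sweeps to CSV
#'
#' @param sweeps List of sweeps as returned by [read_viscosity_sweeps()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viscosity_sweeps <- function(sweeps, path) {
  rows <- do.call(rbind, lapply(sweeps, function(s) {
    data.frame(sample_id = attr(s, "sample_id"),
               treatment = attr(s, "treatment"),
               t_P_h = attr(s, "t_P"),
               shear_rate_per_s = attr(s, "shear_rate"),
               temperature_C = s$temperature_C,
               viscosity_mPa_s = s$viscosity_mPa_s,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format fatty-acid composition table
#'
#' @param path CSV file with header `sample_id,treatment,t_P_h,fa_code,percent`.
#'   Codes must parse per [parse_fa_code()].
#' @return A list of [fa_profile()] objects, one per `(sample_id, t_P_h)`.
#' @export
read_fatty_acid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "treatment", "t_P_h", "fa_code", "percent"),
                "fatty-acid table")
  key <- interaction(df$sample_id, df$t_P_h, drop = TRUE, lex.order = TRUE)
  profiles <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$fa_code)) {
      dup <- g$fa_code[duplicated(g$fa_code)][1L]
      stop_validation("duplicate fatty acid '%s' for sample '%s' at t_P = %g h",
                      dup, g$sample_id[1L], g$t_P_h[1L])
    }
    fa_profile(stats::setNames(g$percent, g$fa_code),
               sample_id = g$sample_id[1L], treatment = g$treatment[1L],
               t_P = g$t_P_h[1L])
  })
  names(profiles) <- NULL
  profiles
}

#' Write fatty-acid profiles to a long-format CSV
#'
#' @param profiles List of [fa_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fatty_acid_table <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = attr(p, "sample_id"),
               treatment = attr(p, "treatment"),
               t_P_h = attr(p, "t_P"),
               fa_code = p$code, percent = p$percent,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read total-polar-compound (TPC) time series
#'
#' @param path CSV file with header `treatment,t_P_h,tpc_percent`.
#' @return A list of series, one per treatment: data frames with columns
#'   `t_P_h`, `tpc_percent` sorted by time, with attribute `treatment`.
#' @export
read_tpc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("treatment", "t_P_h", "tpc_percent"), "TPC table")
  if (nrow(df) == 0L) return(list())
  bad <- which(!is.finite(df$tpc_percent) | df$tpc_percent < 0 |
                 df$tpc_percent > 100)
  if (length(bad) > 0L) {
    stop_validation("TPC outside [0, 100] at data row %d", bad[1L])
  }
  series <- lapply(split(df, df$treatment), function(g) {
    g <- g[order(g$t_P_h), , drop = FALSE]
    if (anyDuplicated(g$t_P_h)) {
      stop_validation("duplicate t_P for treatment '%s'", g$treatment[1L])
    }
    structure(data.frame(t_P_h = g$t_P_h, tpc_percent = g$tpc_percent),
              treatment = g$treatment[1L],
              class = c("tpc_series", "data.frame"))
  })
  names(series) <- NULL
  series
}

#' Write TPC series to CSV
#'
#' @param series List of TPC series as returned by [read_tpc_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tpc_table <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(treatment = attr(s, "treatment"),
               t_P_h = s$t_P_h, tpc_percent = s$tpc_percent,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complete study dataset to a directory
#'
#' Writes `sweeps.csv`, `fatty_acids.csv` and `tpc.csv` in the formats the
#' corresponding readers expect.
#'
#' @param study A study list with components `sweeps`, `profiles`, `tpc`
#'   (see [generate_study()]).
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_viscosity_sweeps(study$sweeps, file.path(dir, "sweeps.csv"))
  write_fatty_acid_table(study$profiles, file.path(dir, "fatty_acids.csv"))
  write_tpc_table(study$tpc, file.path(dir, "tpc.csv"))
  invisible(dir)
}

#' Read a study dataset from a directory written by [write_study()]
#'
#' @param dir Directory containing `sweeps.csv`, `fatty_acids.csv`, `tpc.csv`.
#' @param provenance Free-text provenance label attached to the result.
#' @return A list with components `sweeps`, `profiles`, `tpc`, `provenance`.
#' @export
read_study <- function(dir, provenance = "user") {
  list(sweeps = read_viscosity_sweeps(file.path(dir, "sweeps.csv")),
       profiles = read_fatty_acid_table(file.path(dir, "fatty_acids.csv")),
       tpc = read_tpc_table(file.path(dir, "tpc.csv")),
       provenance = provenance)
}
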