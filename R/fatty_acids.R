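#' Parse fatty-acid shorthand codes
#'
#' Fatty acids are named by the lipid shorthand `C<carbons>:<double_bonds>`,
#' optionally followed by an omega-position suffix such as `"n3"` or `"n-6"`
#' (e.g. `"C18:3n3"` for alpha-linolenic acid). The suffix identifies the
#' positional isomer and is ignored when deriving the carbon and double-bond
#' counts.
#'
#' @param code Character vector of codes such as `"C18:2"` or `"C18:3n3"`.
#' @return A data frame with columns `code`, `carbons` (integer) and
#'   `double_bonds` (integer).
#' @examples
#' parse_fa_code(c("C18:1", "C18:3n3", "C22:0"))
#' @export
parse_fa_code <- function(code) {
  pattern <- "^C([0-9]+):([0-9]+)(n-?[0-9]+)?$"
  ok <- grepl(pattern, code)
  if (any(!ok)) {
    stop_format("unparseable fatty-acid code(s): %s (expected \"C<carbons>:<double_bonds>\" with optional positional suffix)",
                paste(unique(code[!ok]), collapse = ", "))
  }
  carbons <- as.integer(sub(pattern, "\\1", code))
  double_bonds <- as.integer(sub(pattern, "\\2", code))
  bad <- carbons < 2 | double_bonds < 0 | double_bonds >= carbons
  if (any(bad)) {
    stop_validation("implausible fatty-acid code(s): %s (need carbons >= 2 and 0 <= double bonds < carbons)",
                    paste(unique(code[bad]), collapse = ", "))
  }
  data.frame(code = code, carbons = carbons, double_bonds = double_bonds,
             stringsAsFactors = FALSE)
}

#' Construct a fatty-acid profile
#'
#' A profile is one oil sample at one processing time: the mass percent of
#' each reported fatty acid. Carbon and double-bond counts are derived from
#' the codes. Printed composition tables typically sum to slightly less than
#' 100% because minor species are unreported; totals up to a small shortfall
#' are accepted and percents are never renormalised.
#'
#' @param percents Named numeric vector, names are fatty-acid codes
#'   (see [parse_fa_code()]), values mass percent.
#' @param sample_id,treatment Identifying labels.
#' @param t_P Processing (heating) time in hours, `>= 0`.
#' @return An object of class `fa_profile`: a data frame with columns
#'   `code`, `carbons`, `double_bonds`, `percent`, plus attributes
#'   `sample_id`, `treatment`, `t_P`.
#' @examples
#' fa_profile(c("C18:1" = 62.43, "C18:2" = 20.36, "C18:3n3" = 7.46,
#'              "C16:0" = 4.51), sample_id = "demo", t_P = 0)
#' @export
fa_profile <- function(percents, sample_id = "sample", treatment = "C", t_P = 0) {
  if (length(percents) == 0L) {
    stop_validation("empty fatty-acid profile")
  }
  if (is.null(names(percents)) || any(!nzchar(names(percents)))) {
    stop_validation("percents must be a named vector of FA codes")
  }
  if (any(percents < 0)) {
    stop_validation("negative fatty-acid percent in profile '%s'", sample_id)
  }
  if (sum(percents) > 100.5) {
    stop_validation("fatty-acid percents of '%s' sum to %.2f (> 100.5)",
                    sample_id, sum(percents))
  }
  if (anyDuplicated(names(percents))) {
    stop_validation("duplicate fatty-acid code in profile '%s'", sample_id)
  }
  if (!is.numeric(t_P) || length(t_P) != 1L || is.na(t_P) || t_P < 0) {
    stop_validation("t_P must be a single non-negative number of hours")
  }
  spec <- parse_fa_code(names(percents))
  out <- data.frame(code = spec$code, carbons = spec$carbons,
                    double_bonds = spec$double_bonds,
                    percent = unname(percents), stringsAsFactors = FALSE)
  structure(out, sample_id = sample_id, treatment = treatment, t_P = t_P,
            class = c("fa_profile", "data.frame"))
}

#' @export
print.fa_profile <- function(x, ...) {
  cat(sprintf("Fatty-acid profile: %s (treatment %s, t_P = %g h)\n",
              attr(x, "sample_id"), attr(x, "treatment"), attr(x, "t_P")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total: %.2f %%\n", sum(x$percent)))
  invisible(x)
}
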