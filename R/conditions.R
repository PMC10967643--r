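# Classed conditions so callers can distinguish malformed files from
# out-of-range values programmatically.

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oilcascade_format_error", "oilcascade_error")))
}

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oilcascade_validation_error", "oilcascade_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oilcascade_domain_error", "oilcascade_error")))
}

stop_singular <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("oilcascade_singular_error", "oilcascade_error")))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' the presentation of effective carbon numbers), as opposed to [round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(16.2593, 2) # 16.26
#' round_half_up(-0.125, 2)  # -0.13
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
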