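#' Aggregate fatty acids into saturation classes
#'
#' Classes are defined by double-bond count: saturated (0), monounsaturated
#' (1), polyunsaturated (>= 2); total unsaturated is MUFA + PUFA.
#'
#' @param profile An [fa_profile()].
#' @return A one-row data frame with columns `sfa`, `mufa`, `pufa`, `ufa`
#'   (mass percent sums).
#' @examples
#' p <- fa_profile(c("C16:0" = 4.51, "C18:1" = 62.43,
#'                   "C18:2" = 20.36, "C18:3n3" = 7.46))
#' aggregate_fa_classes(p)
#' @export
aggregate_fa_classes <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  sfa <- sum(profile$percent[profile$double_bonds == 0L])
  mufa <- sum(profile$percent[profile$double_bonds == 1L])
  pufa <- sum(profile$percent[profile$double_bonds >= 2L])
  data.frame(sfa = sfa, mufa = mufa, pufa = pufa, ufa = mufa + pufa)
}

#' Effective carbon number (ECN) of a fatty-acid profile
#'
#' ECN summarises chain length and unsaturation in one scalar:
#' \deqn{ECN = \sum_i \frac{P_i}{100} (C_i - db_i)}
#' where \eqn{P_i} is the printed mass percent of fatty acid \eqn{i},
#' \eqn{C_i} its carbon count and \eqn{db_i} its double-bond count. Percents
#' are used exactly as reported, with no renormalisation to a 100% total:
#' composition tables commonly sum to ~97% and the reference ECN tables this
#' package reproduces were computed on the unrenormalised percents. ECN rises
#' as an oil saturates during oxidation.
#'
#' @param profile An [fa_profile()].
#' @return A list with `ecn` (full precision) and `rounded` (two decimals,
#'   half away from zero — the usual table presentation).
#' @examples
#' p <- fa_profile(c("C18:3" = 100))
#' compute_ecn(p)$ecn # 15: one part of (18 - 3)
#' @export
compute_ecn <- function(profile) {
  stopifnot(inherits(profile, "fa_profile"))
  if (nrow(profile) == 0L) stop_validation("empty fatty-acid profile")
  ecn <- sum(profile$percent / 100 * (profile$carbons - profile$double_bonds))
  list(ecn = ecn, rounded = round_half_up(ecn, 2))
}

#' Relative degradation (attrition) rate between two abundances
#'
#' The percent loss of a component relative to its initial abundance:
#' `(initial - final) / initial * 100`. A negative value means growth.
#'
#' @param initial Initial abundance (percent), `> 0`.
#' @param final Final abundance (percent), `>= 0`.
#' @return Degradation rate in percent.
#' @examples
#' degradation_rate(27.82, 23.97) # 13.84% PUFA loss
#' @export
degradation_rate <- function(initial, final) {
  if (any(!is.finite(initial)) || any(initial <= 0)) {
    stop_domain("initial abundance must be positive")
  }
  if (any(!is.finite(final)) || any(final < 0)) {
    stop_domain("final abundance must be non-negative")
  }
  (initial - final) / initial * 100
}

#' Composition summary table for a set of profiles
#'
#' One row per profile: class totals and ECN, in a tidy layout.
#'
#' @param profiles List of [fa_profile()] objects.
#' @return Data frame with columns `sample_id`, `treatment`, `t_P_h`,
#'   `sfa`, `mufa`, `pufa`, `ufa`, `ecn`.
#' @export
composition_summary <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cls <- aggregate_fa_classes(p)
    cbind(data.frame(sample_id = attr(p, "sample_id"),
                     treatment = attr(p, "treatment"),
                     t_P_h = attr(p, "t_P"), stringsAsFactors = FALSE),
          cls, data.frame(ecn = compute_ecn(p)$ecn))
  }))
}
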