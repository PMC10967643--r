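# Accessors for the packaged reference tables (see inst/extdata/README.md
# for provenance and known internal inconsistencies of the printed tables).

rso_file <- function(name) {
  path <- system.file("extdata", name, package = "oilcascade")
  if (!nzchar(path)) stop_format("packaged fixture '%s' not found", name)
  path
}

#' Packaged fatty-acid compositions of heated rapeseed oil
#'
#' Published compositions (mass %) of rapeseed oil with antioxidant
#' treatments at 0/16/32 h of heating at 180 degrees C.
#'
#' @return List of [fa_profile()] objects (15 profiles).
#' @export
rso_fatty_acids <- function() read_fatty_acid_table(rso_file("rso_fatty_acids.csv"))

#' Packaged TPC series of heated rapeseed oil
#'
#' @return List of TPC series, one per treatment (see [read_tpc_table()]).
#' @export
rso_tpc <- function() read_tpc_table(rso_file("rso_tpc.csv"))

#' Packaged published viscosity-model parameters
#'
#' Per-condition Lioumbas and Arrhenius parameters as published (rounded to
#' the printed precision). The raw sweeps behind them were not published.
#'
#' @return Data frame with columns `treatment`, `t_P_h`, `a`, `b`,
#'   `r2_lioumbas`, `mu0`, `Ea`, `r2_arrhenius`.
#' @export
rso_model_params <- function() {
  utils::read.csv(rso_file("rso_model_params.csv"), stringsAsFactors = FALSE)
}

#' Packaged published ECN values
#'
#' @return Data frame with columns `treatment`, `t_P_h`, `ecn`.
#' @export
rso_ecn_reference <- function() {
  utils::read.csv(rso_file("rso_ecn_reference.csv"), stringsAsFactors = FALSE)
}

#' Packaged published fatty-acid class totals
#'
#' @return Data frame with columns `sample_id`, `treatment`, `t_P_h`, `ufa`,
#'   `mufa`, `pufa`.
#' @export
rso_fa_class_reference <- function() {
  utils::read.csv(rso_file("rso_fa_class_reference.csv"),
                  stringsAsFactors = FALSE)
}
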