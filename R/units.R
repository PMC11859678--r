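#' Unit conversions used across the model
#'
#' The package works internally in SI units (mol/m\eqn{^3}, Pa, s, K).
#' Perfusate doses and IC50 values cross the interface in \eqn{\mu}M, with
#' 1 \eqn{\mu}M = 1e-3 mol/m\eqn{^3}. Blood perfusion rates are tabulated in
#' mL blood per minute per kg tissue and are converted to a volumetric
#' fraction per second using the tissue density.
#'
#' @param x numeric vector to convert.
#' @param w_ml_min_kg perfusion rate in mL/min/kg.
#' @param w_per_s perfusion rate in 1/s.
#' @param rho_t tissue density in kg/m\eqn{^3}.
#'
#' @return converted numeric vector.
#' @name units
#' @examples
#' uM_to_mol_m3(160)              # 0.16 mol/m^3
#' perfusion_to_per_s(860, 1079)  # liver perfusion in 1/s
NULL

#' @rdname units
#' @export
uM_to_mol_m3 <- function(x) x * 1e-3

#' @rdname units
#' @export
mol_m3_to_uM <- function(x) x * 1e3

#' @rdname units
#' @export
perfusion_to_per_s <- function(w_ml_min_kg, rho_t) {
  w_ml_min_kg * 1e-6 / 60 * rho_t
}

#' @rdname units
#' @export
perfusion_to_ml_min_kg <- function(w_per_s, rho_t) {
  w_per_s * 60 / (1e-6 * rho_t)
}

per_h_to_per_s <- function(x) x / 3600
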