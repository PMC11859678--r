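#' Organ-specific thermal properties
#'
#' Tissue density, conductivity, heat capacity and blood perfusion rate for
#' the abdominal organs of the bioheat model. Perfusion is tabulated in
#' mL/min/kg and converted to a volumetric rate (1/s) using the tissue
#' density; the skin and peritoneal-wall rows carry no printed density, so a
#' generic soft-tissue density (1050 kg/m\eqn{^3}) is used for their
#' conversion.
#'
#' @return A tibble with one row per organ: `organ`, `w_b_ml_min_kg`,
#'   `rho_t` (kg/m\eqn{^3}), `k_t` (W/m/K), `c_t` (J/kg/K) and the converted
#'   perfusion `w_b` (1/s).
#' @export
#' @examples
#' thermal_properties()
thermal_properties <- function() {
  raw <- hipec_extdata("thermal_properties.yaml")
  def <- raw$defaults
  tbl <- purrr::map_dfr(raw$organs, function(o) {
    tibble::tibble(
      organ = o$organ,
      w_b_ml_min_kg = as.numeric(o$w_b_ml_min_kg),
      rho_t = as.numeric(o$rho_t %||% def$rho_t),
      k_t = as.numeric(o$k_t %||% def$k_t),
      c_t = as.numeric(o$c_t %||% def$c_t)
    )
  })
  dplyr::mutate(tbl, w_b = perfusion_to_per_s(.data$w_b_ml_min_kg, .data$rho_t))
}

#' Blood thermal properties
#'
#' Density and heat capacity of blood used by the perfusion heat sink and the
#' lumped arterial energy balance.
#'
#' @return A list with `rho_b` (kg/m\eqn{^3}) and `c_b` (J/kg/K).
#' @export
blood_properties <- function() {
  b <- hipec_extdata("thermal_properties.yaml")$blood
  list(rho_b = as.numeric(b$rho_b), c_b = as.numeric(b$c_b))
}

#' Transvascular and interstitial transport parameters
#'
#' Constructs the parameter set of the nodule drug-transport model for the
#' tumour or normal-tissue region: vascular hydraulic conductivity `L_p`
#' (m/Pa/s), exchange surface-to-volume ratio `S_over_V` (1/m, proportional
#' to microvascular density), capillary drug permeability `P_c` (m/s),
#' vascular and interstitial fluid pressures `P_v`, `P_i` (Pa), osmotic
#' pressures `pi_v`, `pi_i` (Pa), osmotic partition coefficient `c_osm`,
#' reflection coefficient `sigma`, drug diffusivity `D` (m\eqn{^2}/s) and
#' first-order cellular elimination `beta` (1/s).
#'
#' The default tumour preset uses the interstitial fluid pressure assigned to
#' untreated 2 mm nodules (1.4 kPa) and the baseline microvascular density of
#' 200 1/cm (`S_over_V = 2e4`). The literature alternative for tumour IFP
#' (2.67 kPa) is available via `use_literature_ifp = TRUE`.
#'
#' @param region `"tumor"` or `"normal"`.
#' @param ... named overrides for individual fields.
#' @param use_literature_ifp logical; substitute the literature tumour IFP
#'   preset (2.67 kPa) for the 2 mm-nodule value.
#' @return An object of class `transport_params` (a validated named list).
#' @export
#' @examples
#' transport_params("tumor")
#' transport_params("normal")
transport_params <- function(region = c("tumor", "normal"), ...,
                             use_literature_ifp = FALSE) {
  region <- match.arg(region)
  raw <- hipec_extdata("transport_parameters.yaml")
  p <- lapply(raw[[region]], as.numeric)
  if (use_literature_ifp) {
    if (region != "tumor") stop("literature IFP preset applies to the tumour region")
    p$P_i <- as.numeric(raw$alternatives$tumor_P_i_literature)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown transport parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p$region <- region
  validate_transport_params(p)
}

validate_transport_params <- function(p) {
  num <- c("L_p", "S_over_V", "P_c", "P_v", "P_i", "pi_v", "pi_i",
           "c_osm", "sigma", "D", "beta")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("transport parameter `", f, "` must be a finite number")
    }
  }
  stopifnot(
    p$L_p >= 0, p$S_over_V >= 0, p$P_c >= 0, p$D > 0, p$beta >= 0,
    p$c_osm >= 0, p$c_osm <= 1, p$sigma >= 0, p$sigma <= 1
  )
  structure(p[c(num, "region")], class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params> region:", x$region, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.transport_params <- function(x, ...) {
  tibble::as_tibble(x[setdiff(names(x), "region")]) |>
    dplyr::mutate(region = x$region, .before = 1L)
}

#' Two-compartment pharmacokinetic rate constants
#'
#' First-order transfer rates between the systemic and peripheral
#' compartments (`K12`, `K21`) and the elimination rate (`Ke`), tabulated in
#' 1/h, plus their 1/s conversions and the rat-scale total blood volume used
#' to convert the vascular uptake (mol/s) into a plasma concentration.
#'
#' @return A list with `K12`, `K21`, `Ke` (1/h), `K12_per_s`, `K21_per_s`,
#'   `Ke_per_s`, and `V_blood_m3`.
#' @export
pk_rate_constants <- function() {
  pk <- hipec_extdata("transport_parameters.yaml")$pk
  list(
    K12 = pk$K12_per_h, K21 = pk$K21_per_h, Ke = pk$Ke_per_h,
    K12_per_s = per_h_to_per_s(pk$K12_per_h),
    K21_per_s = per_h_to_per_s(pk$K21_per_h),
    Ke_per_s = per_h_to_per_s(pk$Ke_per_h),
    V_blood_m3 = pk$V_blood_m3
  )
}

#' Temperature-dependent oxaliplatin cytotoxicity for CMS4 colorectal cancer
#'
#' Mean short-term IC50 (\eqn{\mu}M) and thermal enhancement ratio (TER) on
#' the 37-43 degC grid. The TER row is stored verbatim and never recomputed
#' from the IC50 row: the tabulated TER is a mean of per-cell-line ratios,
#' which differs from the ratio of the mean IC50 values.
#'
#' @return A tibble with `temp_c`, `ic50_uM`, `ter`.
#' @export
#' @examples
#' cytotoxicity_table()
cytotoxicity_table <- function() {
  raw <- hipec_extdata("cytotoxicity.yaml")
  tibble::tibble(
    temp_c = as.numeric(raw$temperature_c),
    ic50_uM = as.numeric(raw$ic50_uM),
    ter = as.numeric(raw$ter)
  )
}

#' Interpolate the oxaliplatin IC50 at a treatment temperature
#'
#' Piecewise-linear interpolation of the IC50 grid between 37 and 43 degC.
#' Temperatures outside the grid clamp to the nearest endpoint. Linear
#' interpolation is adopted because it reproduces, within 1 uM, all fourteen
#' IC50 values printed for the organ-surface temperature plateaus of the two
#' catheter setups.
#'
#' @param temp_c temperature(s) in degC.
#' @param table cytotoxicity grid, by default [cytotoxicity_table()].
#' @return IC50 in \eqn{\mu}M (full precision; round for display).
#' @export
#' @examples
#' ic50_at_temperature(40.1) # ~305 uM
ic50_at_temperature <- function(temp_c, table = cytotoxicity_table()) {
  if (any(!is.finite(temp_c))) stop("temperature must be finite")
  approx(table$temp_c, table$ic50_uM, xout = pmin(pmax(temp_c, min(table$temp_c)),
                                                  max(table$temp_c)))$y
}

#' Hyperthermia washout reduction factor y(T)
#'
#' Empirical linear factor multiplying the transvascular washout sink:
#' \deqn{y(T) = -0.04715\,T + 2.744555,} equal to 1 at 37 degC and
#' decreasing under mild hyperthermia (drug washout to the circulation is
#' reduced when the tissue is heated). Negative values are clamped to zero.
#'
#' @param temp_c temperature(s) in degC (intended range 37-43).
#' @return dimensionless factor.
#' @export
#' @examples
#' washout_factor(37) # 1.000005
#' washout_factor(43) # 0.717105
washout_factor <- function(temp_c) {
  if (any(!is.finite(temp_c))) stop("temperature must be finite")
  pmax(-0.04715 * temp_c + 2.744555, 0)
}

#' Vascular-normalization parameter transform for bevacizumab
#'
#' Applies the tumour microenvironment changes attributed to bevacizumab at
#' the two modelled doses. At 0.5 mg/kg the microvascular density falls by
#' 45% (`S_over_V` x 0.55) while vascular leakiness (`L_p`, `P_c`) and the
#' interstitial fluid pressure (1.4 kPa for a 2 mm nodule) are unchanged. At
#' 5 mg/kg the microvascular density falls by 65% (`S_over_V` x 0.35),
#' `L_p` and `P_c` are reduced by 22% (x 0.78), and the IFP drops to
#' 0.25 kPa. Dose 0 is the identity. Normal-tissue parameters are never
#' modified.
#'
#' @param params a tumour-region [transport_params()] object.
#' @param dose bevacizumab dose in mg/kg: 0, 0.5 or 5.
#' @return A new `transport_params` object; the input is not modified.
#' @export
#' @examples
#' apply_bevacizumab(transport_params("tumor"), 5)
apply_bevacizumab <- function(params, dose) {
  stopifnot(inherits(params, "transport_params"))
  if (!dose %in% c(0, 0.5, 5)) {
    stop("unsupported bevacizumab dose: ", dose, " (expected 0, 0.5 or 5 mg/kg)")
  }
  if (dose == 0) return(params)
  if (params$region != "tumor") {
    stop("bevacizumab transform applies to tumour-region parameters only")
  }
  out <- unclass(params)
  if (dose == 0.5) {
    out$S_over_V <- out$S_over_V * 0.55
    out$P_i <- 1400
  } else {
    out$S_over_V <- out$S_over_V * 0.35
    out$L_p <- out$L_p * 0.78
    out$P_c <- out$P_c * 0.78
    out$P_i <- 250
  }
  validate_transport_params(out)
}

#' Collagen-density (stiffness) presets for the tumour interstitium
#'
#' Collagen fibre density in peritoneal colorectal metastases spans roughly
#' 4% (low) to 32% (high). Dense matrices halve the effective drug
#' diffusivity and support about half the microvascular density, so the two
#' presets assign: low - `D` at its reference value and `S_over_V = 2e4` 1/m;
#' high - `D` halved and `S_over_V = 1e4` 1/m. The preset is an absolute
#' assignment from the reference values (a pure function of the base
#' parameter set), so applying presets repeatedly does not compound.
#'
#' @param params a tumour-region [transport_params()] object.
#' @param collagen `"low"` (4%) or `"high"` (32%).
#' @return A new `transport_params` object.
#' @export
#' @examples
#' apply_stiffness(transport_params("tumor"), "high")
apply_stiffness <- function(params, collagen = c("low", "high")) {
  stopifnot(inherits(params, "transport_params"))
  collagen <- match.arg(collagen)
  if (params$region != "tumor") {
    stop("stiffness presets apply to tumour-region parameters only")
  }
  raw <- hipec_extdata("transport_parameters.yaml")
  d_ref <- as.numeric(raw$tumor$D)
  sv_low <- as.numeric(raw$tumor$S_over_V)
  sv_high <- as.numeric(raw$alternatives$tumor_S_over_V_low_mvd)
  out <- unclass(params)
  if (collagen == "low") {
    out$D <- d_ref
    out$S_over_V <- sv_low
  } else {
    out$D <- d_ref * 0.5
    out$S_over_V <- sv_high
  }
  validate_transport_params(out)
}

#' Transvascular Peclet number
#'
#' Ratio of Starling convective to diffusive solute transport across the
#' vessel wall:
#' \deqn{Pe_v = L_p [P_v - P_i - c(\pi_v - \pi_i)] (1-\sigma) / P_c.}
#' With the tabulated tumour constants and a 1.4 kPa IFP the net Starling
#' driving pressure is slightly negative, giving a small negative Peclet
#' number; both signs are handled by [peclet_factor()].
#'
#' @param params a [transport_params()] object with `P_c > 0`.
#' @return dimensionless Peclet number.
#' @export
peclet_number <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  if (params$P_c <= 0) {
    stop("Peclet number undefined for P_c = 0; use a pure-diffusive sink")
  }
  driving <- params$P_v - params$P_i - params$c_osm * (params$pi_v - params$pi_i)
  params$L_p * driving * (1 - params$sigma) / params$P_c
}

#' Peclet modulation factor Pe/(e^Pe - 1)
#'
#' Evaluates the factor multiplying the diffusive transvascular exchange,
#' with the removable singularity at zero handled by a series expansion
#' (used for |Pe| < 1e-6). The factor is strictly decreasing and equals 1
#' at Pe = 0.
#'
#' @param pe Peclet number(s).
#' @return dimensionless factor, same length as `pe`.
#' @export
#' @examples
#' peclet_factor(0)  # 1
#' peclet_factor(1)  # 1 / (e - 1)
peclet_factor <- function(pe) {
  stopifnot(all(is.finite(pe)))
  out <- numeric(length(pe))
  small <- abs(pe) < 1e-6
  out[small] <- 1 - pe[small] / 2 + pe[small]^2 / 12
  out[!small] <- pe[!small] / (exp(pe[!small]) - 1)
  out
}

#' First-order transvascular washout rate coefficient
#'
#' The vascular sink is \eqn{S_v = P_c (S/V) \frac{Pe_v}{e^{Pe_v}-1} y(T) C};
#' this helper returns its rate coefficient (1/s) for given parameters and
#' temperature. `P_c = 0` gives a zero rate.
#'
#' @param params a [transport_params()] object.
#' @param temp_c tissue temperature in degC.
#' @return washout rate in 1/s.
#' @export
vascular_rate <- function(params, temp_c) {
  stopifnot(inherits(params, "transport_params"))
  if (params$P_c <= 0 || params$S_over_V <= 0) return(0)
  params$P_c * params$S_over_V * peclet_factor(peclet_number(params)) *
    washout_factor(temp_c)
}

#' Total drug sink rate
#'
#' Cellular elimination plus temperature-modulated transvascular washout:
#' \eqn{S_c = \beta C + P_c (S/V) \frac{Pe_v}{e^{Pe_v}-1} C\, y(T)}. The
#' hyperthermia factor y(T) applies to the vascular term only.
#'
#' @param conc drug concentration(s), mol/m\eqn{^3} (non-negative).
#' @param params a [transport_params()] object.
#' @param temp_c tissue temperature in degC.
#' @return sink in mol/m\eqn{^3}/s.
#' @export
sink_rate <- function(conc, params, temp_c) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  (params$beta + vascular_rate(params, temp_c)) * conc
}
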