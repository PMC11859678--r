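#' Perfusion schedule for a 30-minute (H)IPEC run
#'
#' Inflow rate, inflow temperature, perfusate oxaliplatin concentration and
#' treatment duration. The defaults are the standard rat-scale protocol:
#' 60 mL/min at 43 degC with 160 uM oxaliplatin for 1800 s.
#'
#' @param flow_rate_ml_min perfusate inflow (= outflow) rate, mL/min.
#' @param inflow_temp_c inflow temperature, degC.
#' @param dose_uM perfusate oxaliplatin concentration, uM.
#' @param t_f treatment duration, s.
#' @return A list of class `perfusion_schedule`.
#' @export
#' @examples
#' perfusion_schedule()
perfusion_schedule <- function(flow_rate_ml_min = 60, inflow_temp_c = 43,
                               dose_uM = 160, t_f = 1800) {
  stopifnot(flow_rate_ml_min > 0, dose_uM >= 0, t_f > 0)
  structure(
    list(flow_rate_ml_min = flow_rate_ml_min, inflow_temp_c = inflow_temp_c,
         dose_uM = dose_uM, t_f = t_f),
    class = "perfusion_schedule"
  )
}

#' Organ-surface temperature and IC50 fixture
#'
#' The steady-state surface temperature plateau induced on each of the seven
#' abdominal organ surfaces for a catheter setup, with the oxaliplatin IC50
#' printed for those temperatures, returned verbatim from the shipped
#' configuration. These plateaus are the canonical temperature inputs of the
#' nodule-scale model.
#'
#' @param setup catheter setup, 1 or 2.
#' @return A tibble with `organ`, `temp_c`, `ic50_uM` and the surrogate
#'   boundary time constant `tau_s`.
#' @export
#' @examples
#' organ_surface_fixture(1)
organ_surface_fixture <- function(setup = 1) {
  if (!setup %in% c(1, 2)) stop("unknown catheter setup: ", setup)
  raw <- hipec_extdata("organ_surface.yaml")[[paste0("setup", setup)]]
  purrr::map_dfr(raw, tibble::as_tibble) |>
    dplyr::mutate(setup = as.integer(setup), .after = "organ")
}

#' Surrogate organ-surface boundary series
#'
#' Generates the per-organ surface drug-concentration and temperature time
#' courses that the nodule solver consumes, standing in for an abdomen-scale
#' perfusion simulation. The surface concentration follows a first-order
#' saturating rise \eqn{C_0 (1 - e^{-t/\tau})} to the perfusate dose, and the
#' temperature is the constant organ plateau of [organ_surface_fixture()]. The
#' default time constants encode that catheter setup 2 covers the organ
#' surfaces faster than setup 1, with the intestine and left kidney as the
#' slow sites of setup 1; downstream fold-change metrics are insensitive to
#' \eqn{\tau} within 60-300 s.
#'
#' @param organ one of the seven organ labels of [organ_surface_fixture()].
#' @param setup catheter setup, 1 or 2.
#' @param schedule a [perfusion_schedule()].
#' @param tau optional override of the saturation time constant, s.
#' @param dt time-grid spacing, s.
#' @return A tibble with `organ`, `setup`, `time_s`, `conc_mol_m3`, `temp_c`;
#'   attributes carry the schedule and tau used.
#' @export
#' @examples
#' b <- generate_boundary("intestine", 1)
#' tail(b)
generate_boundary <- function(organ, setup = 1, schedule = perfusion_schedule(),
                              tau = NULL, dt = 1) {
  fixture <- organ_surface_fixture(setup)
  row <- fixture[fixture$organ == organ, ]
  if (nrow(row) != 1L) {
    stop("unknown organ: ", organ, " (expected one of ",
         paste(fixture$organ, collapse = ", "), ")")
  }
  tau <- tau %||% row$tau_s
  stopifnot(tau > 0, dt > 0)
  times <- seq(0, schedule$t_f, by = dt)
  c0 <- uM_to_mol_m3(schedule$dose_uM)
  out <- tibble::tibble(
    organ = organ,
    setup = as.integer(setup),
    time_s = times,
    conc_mol_m3 = c0 * (1 - exp(-times / tau)),
    temp_c = row$temp_c
  )
  attr(out, "schedule") <- schedule
  attr(out, "tau_s") <- tau
  out
}
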