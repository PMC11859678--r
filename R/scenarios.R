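#' Define a treatment scenario
#'
#' A scenario is one arm of a simulated experiment: perfusate dose and
#' modality plus the tumour-microenvironment transforms (bevacizumab dose,
#' collagen-density preset, permeability multiplier). Host-tissue parameters
#' are never touched by scenario transforms.
#'
#' @param arm scenario label, e.g. `"control"`, `"bev_0.5"`.
#' @param bevacizumab_dose 0, 0.5 or 5 (mg/kg).
#' @param collagen `NA`, `"low"` (4%) or `"high"` (32%) fibre density.
#' @param permeability_multiplier factor applied to the baseline capillary
#'   permeability before any bevacizumab transform (> 0).
#' @param oxaliplatin_dose_uM perfusate dose, \eqn{\mu}M.
#' @param modality `"HIPEC"` (heated, organ plateau temperatures) or
#'   `"IPEC"` (normothermic, 37 degC).
#' @return A one-row tibble; rows from several calls can be bound together
#'   into an experiment's scenario table.
#' @export
#' @examples
#' dplyr::bind_rows(
#'   scenario_spec("control"),
#'   scenario_spec("bev_5", bevacizumab_dose = 5)
#' )
scenario_spec <- function(arm = "control", bevacizumab_dose = 0,
                          collagen = NA_character_,
                          permeability_multiplier = 1,
                          oxaliplatin_dose_uM = 160,
                          modality = c("HIPEC", "IPEC")) {
  modality <- match.arg(modality)
  if (!bevacizumab_dose %in% c(0, 0.5, 5)) {
    stop("unsupported bevacizumab dose: ", bevacizumab_dose)
  }
  if (!is.na(collagen) && !collagen %in% c("low", "high")) {
    stop("collagen must be NA, \"low\" or \"high\"")
  }
  stopifnot(permeability_multiplier > 0, oxaliplatin_dose_uM >= 0)
  tibble::tibble(
    arm = arm,
    bevacizumab_dose = bevacizumab_dose,
    collagen = collagen,
    permeability_multiplier = permeability_multiplier,
    oxaliplatin_dose_uM = oxaliplatin_dose_uM,
    modality = modality
  )
}

#' Resolve a scenario to tumour-region transport parameters
#'
#' Applies, in order: the collagen-density preset, the baseline permeability
#' multiplier, and the bevacizumab transform. The order matters: the
#' permeability sweep rescales the *baseline* capillary permeability, and
#' the 5 mg/kg bevacizumab arm then reduces the rescaled permeability by a
#' further 22%.
#'
#' @param spec one row from [scenario_spec()].
#' @param base tumour-region base parameters.
#' @return A [transport_params()] object.
#' @export
resolve_parameters <- function(spec, base = transport_params("tumor")) {
  p <- base
  if (!is.na(spec$collagen)) p <- apply_stiffness(p, spec$collagen)
  if (spec$permeability_multiplier != 1) {
    p <- validate_transport_params(modifyList(
      unclass(p), list(P_c = p$P_c * spec$permeability_multiplier)
    ))
  }
  apply_bevacizumab(p, spec$bevacizumab_dose)
}

#' Run one scenario cell (scenario x organ x setup)
#'
#' Chains boundary generation, the nodule solve, the systemic PK model and
#' the evaluation metrics for one tumour location.
#'
#' @param spec one row from [scenario_spec()].
#' @param organ organ label; `setup` catheter setup (1 or 2).
#' @param setup catheter setup.
#' @param numerics list of numerical settings: `mesh_spacing`, `dt`, `t_f`,
#'   `snapshot_every`, `tau` (boundary override), `peritoneal_area_m2`,
#'   `deff_rule`.
#' @param keep_fit return the `nodule_fit` in a list-column.
#' @return A one-row tibble of metrics (tumour AUC, effective penetration
#'   depth raw and normalized, plasma AUC, PA ratio) plus the scenario hash.
#' @export
run_scenario <- function(spec, organ, setup = 1, numerics = list(),
                         keep_fit = FALSE) {
  num <- modifyList(list(mesh_spacing = 5e-5, dt = 0.5, t_f = 1800,
                         snapshot_every = 120L, tau = NULL,
                         peritoneal_area_m2 = 0.0125,
                         deff_rule = "contiguous"), numerics)
  schedule <- perfusion_schedule(dose_uM = spec$oxaliplatin_dose_uM,
                                 t_f = num$t_f)
  boundary <- generate_boundary(organ, setup, schedule, tau = num$tau,
                                dt = min(num$dt, 1))
  eval_temp <- boundary$temp_c[1L]
  if (spec$modality == "IPEC") boundary$temp_c <- 37
  params <- resolve_parameters(spec)
  fit <- solve_nodule(
    boundary,
    tumor_params = params,
    geometry = nodule_geometry(mesh_spacing = num$mesh_spacing),
    t_f = num$t_f, dt = num$dt, snapshot_every = num$snapshot_every
  )
  ic50 <- ic50_at_temperature(if (spec$modality == "HIPEC") eval_temp else 37)
  d_eff <- effective_penetration_depth(fit, ic50_uM = ic50,
                                       rule = num$deff_rule)
  src <- peritoneal_source(fit, peritoneal_area_m2 = num$peritoneal_area_m2)
  pk <- integrate_pk(src)
  auc_t <- tumor_auc(fit)
  out <- dplyr::bind_cols(
    spec,
    tibble::tibble(
      organ = organ, setup = as.integer(setup), temp_c = fit$temp_c,
      eval_temp_c = if (spec$modality == "HIPEC") eval_temp else 37,
      ic50_uM = ic50,
      tumor_auc_mol_s_m3 = auc_t,
      d_eff_m = d_eff,
      d_eff_norm = d_eff / fit$geometry$tumor_diameter,
      plasma_auc_uM_s = pk$plasma_auc_uM_s,
      pa = pa_ratio(auc_t, pk$plasma_auc_uM_s),
      mass_balance_rel_error = fit$mass_balance$rel_error,
      scenario_hash = rlang::hash(list(spec, organ, setup, num,
                                       unclass(params)))
    )
  )
  if (keep_fit) out$fit <- list(fit)
  out
}

#' Shipped experiment configurations
#'
#' Pre-assembled configurations mirroring the four analyses of the study
#' design: the organ sweep of treatment arms across both catheter setups,
#' the collagen-density comparison and the permeability sweep at the
#' intestine site, and the dose-equivalence grid.
#'
#' @param name configuration name.
#' @param ... numerics overrides stored in the config (e.g. `mesh_spacing`,
#'   `dt`).
#' @return A list of class `hipec_config` with elements `name`, `scenarios`
#'   (tibble), `organs`, `setups` and `numerics`.
#' @export
#' @examples
#' experiment_config("figure4_stiffness", mesh_spacing = 2e-4, dt = 2)
experiment_config <- function(name = c("figure3_organ_sweep",
                                       "figure4_stiffness",
                                       "figure4_permeability",
                                       "figure5_dose_equivalence"), ...) {
  name <- match.arg(name)
  organs <- organ_surface_fixture(1)$organ
  cfg <- switch(name,
    figure3_organ_sweep = list(
      scenarios = dplyr::bind_rows(
        scenario_spec("control"),
        scenario_spec("bev_0.5", bevacizumab_dose = 0.5),
        scenario_spec("bev_5", bevacizumab_dose = 5)
      ),
      organs = organs, setups = c(1L, 2L)
    ),
    figure4_stiffness = list(
      scenarios = dplyr::bind_rows(purrr::map(
        c("low", "high"),
        \(cf) dplyr::bind_rows(
          scenario_spec(paste0("control_", cf), collagen = cf),
          scenario_spec(paste0("bev_0.5_", cf), 0.5, collagen = cf),
          scenario_spec(paste0("bev_5_", cf), 5, collagen = cf)
        )
      )),
      organs = "intestine", setups = 1L
    ),
    figure4_permeability = list(
      scenarios = dplyr::bind_rows(purrr::map(
        c(0.2, 0.5, 1, 2, 5),
        \(m) dplyr::bind_rows(
          scenario_spec(paste0("control_x", m), permeability_multiplier = m),
          scenario_spec(paste0("bev_5_x", m), 5, permeability_multiplier = m)
        )
      )),
      organs = "intestine", setups = 1L
    ),
    figure5_dose_equivalence = list(
      scenarios = dplyr::bind_rows(
        scenario_spec("control"),
        scenario_spec("bev_0.5", bevacizumab_dose = 0.5),
        scenario_spec("bev_5", bevacizumab_dose = 5)
      ),
      organs = organs, setups = 1L,
      dose_grid = seq(160, 320, by = 20)
    )
  )
  cfg$name <- name
  cfg$numerics <- list(...)
  structure(cfg, class = "hipec_config")
}

#' Validate an experiment configuration
#'
#' Checks that every scenario row resolves to a full parameter set, that the
#' organ and setup labels exist, and that the configuration round-trips
#' losslessly through serialization.
#'
#' @param config a `hipec_config` (or compatible list).
#' @return `TRUE` invisibly; errors describe the first problem found.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config), is.data.frame(config$scenarios),
            length(config$organs) > 0L, all(config$setups %in% c(1L, 2L)))
  for (i in seq_len(nrow(config$scenarios))) {
    resolve_parameters(config$scenarios[i, ])
  }
  for (s in config$setups) {
    known <- organ_surface_fixture(s)$organ
    bad <- setdiff(config$organs, known)
    if (length(bad)) stop("unknown organ(s) for setup ", s, ": ",
                          paste(bad, collapse = ", "))
  }
  rt <- unserialize(serialize(config, NULL))
  if (!identical(rt, config)) stop("configuration does not round-trip")
  invisible(TRUE)
}

#' List the scenario cells of a configuration
#'
#' @param config a `hipec_config`.
#' @return A tibble with one row per scenario x organ x setup cell.
#' @export
list_scenarios <- function(config) {
  grid <- tidyr::expand_grid(
    arm = config$scenarios$arm,
    organ = config$organs,
    setup = as.integer(config$setups)
  )
  dplyr::left_join(grid, config$scenarios, by = "arm")
}

#' Run a full experiment configuration
#'
#' Executes boundary generation, the nodule solve, the PK chain and the
#' metrics for every scenario x organ x setup cell. The pipeline is fully
#' deterministic: no stage draws random numbers, and every output row
#' carries a hash of its fully resolved parameters and numerical settings.
#' A failing cell is recorded with its error message and does not abort the
#' remaining cells.
#'
#' @param config from [experiment_config()] or assembled by hand.
#' @param numerics numerical settings overriding the config's own (see
#'   [run_scenario()]).
#' @param output_dir optional directory; when given, results are written as
#'   `results.csv` and `summary.json` with a provenance log.
#' @param quiet suppress progress messages.
#' @return A tibble of per-cell results (error rows carry `error`).
#' @export
run_experiment <- function(config, numerics = list(), output_dir = NULL,
                           quiet = TRUE) {
  validate_config(config)
  num <- modifyList(config$numerics %||% list(), numerics)
  cells <- list_scenarios(config)
  res <- purrr::pmap(
    list(cells$arm, cells$organ, cells$setup),
    function(arm, organ, setup) {
      spec <- config$scenarios[config$scenarios$arm == arm, ]
      if (!quiet) message("running ", arm, " / ", organ, " / setup ", setup)
      tryCatch(
        run_scenario(spec, organ, setup, numerics = num),
        error = function(e) {
          dplyr::bind_cols(spec, tibble::tibble(
            organ = organ, setup = as.integer(setup),
            error = conditionMessage(e)
          ))
        }
      )
    }
  )
  out <- dplyr::bind_rows(res)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out[, setdiff(names(out), "fit")],
                     file.path(output_dir, "results.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = config$name, numerics = num,
           n_cells = nrow(out),
           arms = unique(out$arm)),
      file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
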