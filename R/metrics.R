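#' Volume-weighted mean tumour concentration at a time point
#'
#' The spatial average of the concentration over the tumour region
#' (axisymmetric cell volumes), linearly interpolated between stored time
#' points.
#'
#' @param fit a [solve_nodule()] result.
#' @param t time, s (within the simulated horizon).
#' @return mean concentration, mol/m\eqn{^3}.
#' @export
mean_concentration <- function(fit, t) {
  stopifnot(inherits(fit, "nodule_fit"))
  if (fit$tumor_volume_m3 <= 0) stop("fit has an empty tumour region")
  if (any(t < 0 | t > max(fit$times))) stop("time outside the stored horizon")
  approx(fit$times, fit$mean_tumor, xout = t)$y
}

#' Tumour exposure: area under the mean-concentration curve
#'
#' Trapezoidal integral of the volume-averaged tumour concentration over the
#' treatment, in mol s / m\eqn{^3} (multiply by 1000 for \eqn{\mu}M s).
#'
#' @param fit a [solve_nodule()] result.
#' @return AUC in mol s / m\eqn{^3}.
#' @export
tumor_auc <- function(fit) {
  stopifnot(inherits(fit, "nodule_fit"))
  if (fit$tumor_volume_m3 <= 0) stop("fit has an empty tumour region")
  if (length(fit$times) < 2L) stop("need at least two snapshots")
  trapz(fit$times, fit$mean_tumor)
}

# depth of the contiguous exceedance region from the exposed pole, with
# linear interpolation of the crossing between cell centres; conc/depth are
# the axis profile restricted to the tumour, thr the threshold (mol/m^3)
axis_crossing_depth <- function(depth, conc, thr, diameter, surface_conc,
                                rule = c("contiguous", "any")) {
  rule <- match.arg(rule)
  above <- conc >= thr
  if (rule == "any") {
    if (!any(above)) return(0)
    i <- max(which(above))
    if (i == length(conc)) return(diameter)
    # interpolate the crossing beyond the deepest exceeding cell
    d <- depth[i] + (depth[i + 1L] - depth[i]) *
      (conc[i] - thr) / (conc[i] - conc[i + 1L])
    return(min(d, diameter))
  }
  if (!above[1L]) {
    # surface value may still exceed the threshold inside the first half-cell
    if (surface_conc >= thr && surface_conc > conc[1L]) {
      return(depth[1L] * (surface_conc - thr) / (surface_conc - conc[1L]))
    }
    return(0)
  }
  i <- if (all(above)) length(conc) else min(which(!above)) - 1L
  if (i == length(conc)) return(diameter)
  d <- depth[i] + (depth[i + 1L] - depth[i]) *
    (conc[i] - thr) / (conc[i] - conc[i + 1L])
  min(d, diameter)
}

#' Effective penetration depth referenced to the IC50
#'
#' Depth of tumour along the symmetry axis, measured from the exposed pole,
#' over which the end-of-treatment drug concentration exceeds 10% of the
#' IC50 at the treatment temperature (for heated chemoperfusion the
#' temperature-specific IC50 embodies the thermal enhancement of
#' cytotoxicity; for normothermic perfusion use the 37 degC IC50). The depth
#' is capped at the tumour diameter.
#'
#' Two readings of the exceedance region are available: `"contiguous"`
#' (default) returns the depth of the unbroken exceedance region from the
#' exposed surface - the standard penetration-depth reading; `"any"` returns
#' the largest exceeding depth, which can include tissue near the embedded
#' pole supplied through the host and is reported for sensitivity only.
#'
#' @param fit a [solve_nodule()] result.
#' @param ic50_uM IC50 at the evaluation temperature, \eqn{\mu}M; defaults
#'   to [ic50_at_temperature()] at the fit temperature (`modality = "HIPEC"`)
#'   or at 37 degC (`modality = "IPEC"`).
#' @param modality `"HIPEC"` or `"IPEC"` (selects the default IC50 only).
#' @param threshold_frac fraction of the IC50 used as threshold (0.1).
#' @param at `"final"` (end-of-treatment field, default) or `"max"`
#'   (pointwise maximum over stored snapshots).
#' @param rule exceedance reading, see Details.
#' @param normalized divide by the tumour diameter.
#' @return depth in m (or a fraction of the diameter when `normalized`).
#' @export
effective_penetration_depth <- function(fit, ic50_uM = NULL,
                                        modality = c("HIPEC", "IPEC"),
                                        threshold_frac = 0.1,
                                        at = c("final", "max"),
                                        rule = c("contiguous", "any"),
                                        normalized = FALSE) {
  stopifnot(inherits(fit, "nodule_fit"))
  modality <- match.arg(modality)
  at <- match.arg(at)
  rule <- match.arg(rule)
  diameter <- fit$geometry$tumor_diameter
  if (diameter <= 0) stop("fit has an empty tumour region")
  ic50_uM <- ic50_uM %||%
    ic50_at_temperature(if (modality == "HIPEC") fit$temp_c else 37)
  thr <- uM_to_mol_m3(threshold_frac * ic50_uM)

  snaps <- fit$axis_snapshots
  if (at == "final") {
    prof <- dplyr::filter(snaps, .data$time_s == max(snaps$time_s))
  } else {
    prof <- snaps |>
      dplyr::group_by(.data$depth_m, .data$region) |>
      dplyr::summarise(conc_mol_m3 = max(.data$conc_mol_m3), .groups = "drop") |>
      dplyr::arrange(.data$depth_m)
  }
  prof <- dplyr::filter(prof, .data$region == "tumor")
  d <- axis_crossing_depth(prof$depth_m, prof$conc_mol_m3, thr, diameter,
                           surface_conc = max(prof$conc_mol_m3), rule = rule)
  if (normalized) d / diameter else d
}

#' Pharmacokinetic advantage ratio
#'
#' Ratio of the tumour AUC to the plasma AUC after conversion to a common
#' concentration-time unit (\eqn{\mu}M s).
#'
#' @param tumor_auc_mol_s_m3 tumour AUC from [tumor_auc()], mol s/m\eqn{^3}.
#' @param plasma_auc_uM_s plasma AUC from [integrate_pk()], \eqn{\mu}mol s/L.
#' @return dimensionless PA ratio.
#' @export
pa_ratio <- function(tumor_auc_mol_s_m3, plasma_auc_uM_s) {
  if (any(plasma_auc_uM_s <= 0)) stop("plasma AUC must be positive")
  mol_m3_to_uM(tumor_auc_mol_s_m3) / plasma_auc_uM_s
}

#' Monotherapy dose matching a combination arm's penetration
#'
#' Searches a perfusate dose grid for the oxaliplatin monotherapy dose whose
#' median effective penetration depth across the organ sites is closest to
#' that of a combination (vascular-normalization) arm at the reference dose.
#' Because the transport chain is linear in the perfusate concentration, the
#' monotherapy field at any grid dose is the reference-dose control field
#' scaled by the dose ratio, so one control solve per organ suffices; this
#' linearity is verified in the package tests. Ties resolve to the lower
#' dose.
#'
#' @param control_fits named list (by organ) of control-arm [solve_nodule()]
#'   fits at the reference dose.
#' @param combo_fits named list (by organ) of combination-arm fits at the
#'   reference dose; organ names must match `control_fits`.
#' @param ic50_uM named vector of IC50 values (\eqn{\mu}M) per organ at the
#'   evaluation temperatures.
#' @param dose_grid candidate monotherapy doses, \eqn{\mu}M.
#' @param ref_dose_uM perfusate dose at which the fits were run.
#' @param ... passed to [effective_penetration_depth()] (e.g. `rule`).
#' @return the selected dose (\eqn{\mu}M), with the per-dose median depths
#'   as attribute `"medians"`.
#' @export
dose_equivalence_search <- function(control_fits, combo_fits, ic50_uM,
                                    dose_grid = seq(160, 320, by = 20),
                                    ref_dose_uM = 160, ...) {
  if (!length(dose_grid)) stop("empty dose grid")
  organs <- names(control_fits)
  stopifnot(length(organs) > 0L, setequal(organs, names(combo_fits)),
            all(organs %in% names(ic50_uM)))
  combo_med <- median(purrr::map_dbl(
    organs, \(o) effective_penetration_depth(combo_fits[[o]],
                                             ic50_uM = ic50_uM[[o]], ...)
  ))
  med_at_dose <- purrr::map_dbl(dose_grid, function(d) {
    median(purrr::map_dbl(organs, function(o) {
      # linear scaling of the control field to dose d
      effective_penetration_depth(control_fits[[o]],
                                  ic50_uM = ic50_uM[[o]] * ref_dose_uM / d, ...)
    }))
  })
  pick <- dose_grid[which.min(abs(med_at_dose - combo_med))]
  structure(pick, medians = setNames(med_at_dose, dose_grid),
            combo_median = combo_med)
}

#' Across-organ summary of scenario results
#'
#' Per-arm median and interquartile range of the normalized effective
#' penetration depth, with fold changes of the arm medians against a control
#' arm. Quartiles use linear interpolation (the default convention), which
#' matters visibly with seven organ sites.
#'
#' @param results a tidy results table (e.g. from [run_experiment()]) with
#'   columns `arm`, `organ`, `d_eff_norm` and `tumor_auc_mol_s_m3`.
#' @param control name of the control arm (default `"control"`).
#' @return A tibble with one row per arm: `median`, `q25`, `q75` of
#'   `d_eff_norm` and `fold_median` vs the control arm.
#' @export
summarize_across_organs <- function(results, control = "control") {
  stopifnot(all(c("arm", "organ", "d_eff_norm") %in% names(results)))
  arms <- split(results, results$arm)
  org0 <- sort(unique(results$organ[results$arm == control]))
  for (a in names(arms)) {
    if (!setequal(arms[[a]]$organ, org0)) {
      stop("arm `", a, "` does not cover the same organ set as the control")
    }
  }
  out <- results |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median = median(.data$d_eff_norm),
      q25 = quantile(.data$d_eff_norm, 0.25, names = FALSE),
      q75 = quantile(.data$d_eff_norm, 0.75, names = FALSE),
      .groups = "drop"
    )
  ctrl_med <- out$median[out$arm == control]
  if (!length(ctrl_med)) stop("control arm `", control, "` not found")
  dplyr::mutate(out, fold_median = .data$median / ctrl_med)
}

#' Per-organ fold change of a metric against a control arm
#'
#' @param results tidy results with columns `arm`, `organ` and the metric.
#' @param metric column name to compare (default `"tumor_auc_mol_s_m3"`).
#' @param control control arm name.
#' @return A tibble `arm`, `organ`, `fold` (arm value / control value).
#' @export
fold_change_by_organ <- function(results, metric = "tumor_auc_mol_s_m3",
                                 control = "control") {
  stopifnot(all(c("arm", "organ", metric) %in% names(results)))
  keys <- intersect(c("organ", "setup"), names(results))
  ctrl <- results[results$arm == control, c(keys, metric)]
  names(ctrl)[names(ctrl) == metric] <- ".control_value"
  out <- dplyr::inner_join(results, ctrl, by = keys)
  if (nrow(out) != nrow(results)) stop("mismatched organ sets between arms")
  out$fold <- out[[metric]] / out$.control_value
  out[, c("arm", keys, "fold")]
}
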