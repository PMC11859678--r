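#' Plot a nodule concentration-depth profile
#'
#' End-of-treatment concentration along the symmetry axis, with the tumour /
#' host regions distinguished and an optional 10%-IC50 threshold line.
#'
#' @param object a [solve_nodule()] result.
#' @param ic50_uM optional IC50 (\eqn{\mu}M) to draw the threshold at.
#' @param threshold_frac fraction of the IC50 drawn (0.1).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nodule_fit <- function(object, ic50_uM = NULL, threshold_frac = 0.1,
                                ...) {
  prof <- axis_profile(object)
  p <- ggplot2::ggplot(prof, ggplot2::aes(
    x = .data$depth_m * 1e3, y = mol_m3_to_uM(.data$conc_mol_m3),
    colour = .data$region
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "depth from exposed pole [mm]",
                  y = "oxaliplatin [µM]", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ic50_uM)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_frac * ic50_uM,
                                 linetype = "dashed")
  }
  p
}

#' Plot plasma and peripheral oxaliplatin trajectories
#'
#' @param object a [integrate_pk()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pk_fit <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(-"time_s", names_to = "compartment",
                        values_to = "conc_uM") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s / 60, y = .data$conc_uM,
                                 colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time [min]", y = "concentration [µmol/L]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of normalized penetration depths across organ sites
#'
#' Mirrors the across-organ evaluation of the treatment arms: one box per
#' arm of the normalized effective penetration depth over the organ sites.
#'
#' @param results tidy results from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_penetration_summary <- function(results) {
  stopifnot(all(c("arm", "d_eff_norm") %in% names(results)))
  ggplot2::ggplot(results, ggplot2::aes(x = .data$arm, y = .data$d_eff_norm)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$organ)) +
    ggplot2::labs(x = NULL, y = "normalized effective penetration depth") +
    ggplot2::theme_minimal()
}

#' Plot a bioheat slab temperature profile
#'
#' @param object a [bioheat_slab()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bioheat_fit <- function(object, ...) {
  df <- tidy(object)
  df_final <- df[df$time_s == max(df$time_s), ]
  ggplot2::ggplot(df_final, ggplot2::aes(x = .data$position_m * 1e3,
                                         y = .data$temp_c)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "depth [mm]", y = "temperature [°C]") +
    ggplot2::theme_minimal()
}
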