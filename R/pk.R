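# matrix-exponential stepping for a linear system x' = A x + b with
# piecewise-constant b: x+ = E x + M b, E = e^(A dt), M = int_0^dt e^(As) ds.
# M is computed by series (A dt is always small here), which also covers
# singular A (e.g. a zero elimination rate).
expm_stepper <- function(a, dt) {
  e <- as.matrix(Matrix::expm(Matrix::Matrix(a * dt)))
  m <- diag(nrow(a)) * dt
  term <- m
  for (k in 2:12) {
    term <- (term %*% a) * (dt / k)
    m <- m + term
    if (max(abs(term)) < 1e-16 * max(abs(m))) break
  }
  list(E = e, M = m)
}

#' Two-compartment systemic pharmacokinetics driven by tissue uptake
#'
#' Integrates the linear systemic/peripheral compartment system
#' \deqn{\dot C_{sys} = S_v/V_b - (K_{12}+K_e) C_{sys} + K_{21} C_{per},\quad
#'       \dot C_{per} = K_{12} C_{sys} - K_{21} C_{per}}
#' where the source \eqn{S_v(t)} (mol/s) is the volume-integrated vascular
#' drug uptake from the tissue. The integrator steps exactly through the
#' matrix exponential on each source interval (piecewise-constant source,
#' interval-mean value), so it is stiff-safe and preserves non-negativity
#' for non-negative sources.
#'
#' @param source a tibble with `time_s` and `source_mol_s` (e.g. from
#'   [peritoneal_source()]).
#' @param rates rate constants from [pk_rate_constants()] (1/h values are
#'   converted internally).
#' @param V_blood total blood volume, m\eqn{^3}.
#' @return An object of class `pk_fit`; [tidy()] gives the trajectories in
#'   \eqn{\mu}mol/L, [glance()] the plasma AUC (\eqn{\mu}mol s / L).
#' @export
#' @examples
#' src <- tibble::tibble(time_s = 0:1800, source_mol_s = 1e-9)
#' fit <- integrate_pk(src)
#' glance(fit)
integrate_pk <- function(source, rates = pk_rate_constants(),
                         V_blood = rates$V_blood_m3) {
  stopifnot(is.data.frame(source),
            all(c("time_s", "source_mol_s") %in% names(source)))
  k12 <- rates$K12_per_s %||% per_h_to_per_s(rates$K12)
  k21 <- rates$K21_per_s %||% per_h_to_per_s(rates$K21)
  ke <- rates$Ke_per_s %||% per_h_to_per_s(rates$Ke)
  if (any(c(k12, k21, ke) < 0)) stop("rate constants must be non-negative")
  stopifnot(V_blood > 0)

  tt <- source$time_s
  ss <- source$source_mol_s
  n <- length(tt)
  stopifnot(n >= 2L, !is.unsorted(tt))
  a <- matrix(c(-(k12 + ke), k12, k21, -k21), 2L, 2L)
  dts <- diff(tt)
  x <- matrix(0, 2L, n) # mol/m^3 (systemic, peripheral)
  step <- NULL
  last_dt <- NA_real_
  for (i in seq_len(n - 1L)) {
    if (is.na(last_dt) || abs(dts[i] - last_dt) > 1e-12) {
      step <- expm_stepper(a, dts[i])
      last_dt <- dts[i]
    }
    b <- c(mean(ss[i:(i + 1L)]) / V_blood, 0)
    x[, i + 1L] <- step$E %*% x[, i] + step$M %*% b
  }
  traj <- tibble::tibble(
    time_s = tt,
    c_sys_uM = mol_m3_to_uM(x[1L, ]),
    c_per_uM = mol_m3_to_uM(x[2L, ])
  )
  structure(
    list(trajectory = traj, rates = rates, V_blood = V_blood,
         plasma_auc_uM_s = trapz(traj$time_s, traj$c_sys_uM)),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> plasma AUC =", signif(x$plasma_auc_uM_s, 4), "uM s\n")
  invisible(x)
}

#' @describeIn integrate_pk systemic and peripheral trajectories.
#' @param x a `pk_fit`.
#' @param ... unused.
#' @export
tidy.pk_fit <- function(x, ...) x$trajectory

#' @describeIn integrate_pk one-row summary.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    plasma_auc_uM_s = x$plasma_auc_uM_s,
    c_sys_final_uM = tail(x$trajectory$c_sys_uM, 1L),
    c_per_final_uM = tail(x$trajectory$c_per_uM, 1L),
    V_blood_m3 = x$V_blood
  )
}

#' Whole-peritoneum vascular uptake source for the systemic compartment
#'
#' Builds the plasma source term (mol/s) from a nodule simulation as the sum
#' of (i) the vascular washout integrated over the simulated nodule domain
#' (tumour plus surrounding host block) and (ii) an effective normal-tissue
#' exchange term standing in for abdomen-wide uptake by the drug-bathed
#' peritoneum: a surface layer of depth `layer_depth` over the total
#' peritoneal area, held in quasi-steady diffusion-elimination balance with
#' the cavity-side boundary concentration. The quasi-steady layer mean is
#' \eqn{\bar C = C_b (\ell/\delta)\tanh(\delta/\ell)} with the normal-tissue
#' decay length \eqn{\ell = \sqrt{D/(\beta + k_v)}}, and the vascular uptake
#' rate applies to that mean.
#'
#' The peritoneal area and layer depth are surrogate, rat-scale quantities:
#' they set the absolute plasma concentration, and they attenuate - but do
#' not create - between-scenario differences in the pharmacokinetic
#' advantage ratio, because the normal-tissue term is identical across
#' tumour-parameter scenarios at a given dose.
#'
#' @param fit a [solve_nodule()] result.
#' @param peritoneal_area_m2 total peritoneal surface area engaged in
#'   exchange (default 0.0125 m\eqn{^2}, allometric rat-scale estimate).
#' @param layer_depth exchange-layer depth, m (default 1 mm).
#' @return A tibble with `time_s` and `source_mol_s`.
#' @export
peritoneal_source <- function(fit, peritoneal_area_m2 = 0.0125,
                              layer_depth = 1e-3) {
  stopifnot(inherits(fit, "nodule_fit"), peritoneal_area_m2 >= 0,
            layer_depth > 0)
  np <- fit$host_params
  kv <- vascular_rate(np, fit$temp_c)
  ell <- sqrt(np$D / (np$beta + kv))
  layer_mean <- (ell / layer_depth) * tanh(layer_depth / ell)
  normal_term <- kv * peritoneal_area_m2 * layer_depth * layer_mean *
    fit$boundary_conc
  tibble::tibble(
    time_s = fit$times,
    source_mol_s = fit$sv_tumor + fit$sv_host + normal_term
  )
}
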