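#' Lumped arterial thermal state
#'
#' State of the whole-body arterial blood pool used by the bioheat model:
#' arterial temperature, blood volume and the heat-rate terms of the lumped
#' energy balance. The skin and tail losses are modelled as configurable
#' linear exchanges \eqn{hA (T_a - T_{env})}; metabolic heat defaults to
#' zero with a configuration hook.
#'
#' @param T_a arterial temperature, degC.
#' @param V_b total blood volume, m\eqn{^3} (rat-scale default 16 mL).
#' @param q_m metabolic heat gain, W.
#' @param hA_skin,hA_tail linear loss coefficients, W/K.
#' @param T_env environment temperature, degC.
#' @param blood blood density/heat capacity from [blood_properties()].
#' @return A list of class `arterial_state`.
#' @export
arterial_state <- function(T_a = 37, V_b = 1.6e-5, q_m = 0,
                           hA_skin = 0.05, hA_tail = 0.02, T_env = 22,
                           blood = blood_properties()) {
  stopifnot(V_b > 0)
  structure(
    list(T_a = T_a, V_b = V_b, q_m = q_m, hA_skin = hA_skin,
         hA_tail = hA_tail, T_env = T_env, rho_b = blood$rho_b,
         c_b = blood$c_b),
    class = "arterial_state"
  )
}

#' Update the arterial temperature from the lumped heat balance
#'
#' \deqn{\Delta T_a = (q_m + q_{therm} - q_{skin} - q_{tail})\,\Delta t /
#'  (\rho_b c_b V_b)} where \eqn{q_{therm}} is the net heat gained by blood
#' perfusing the (warmer) tissue. The update is linear in the flux balance:
#' balanced fluxes leave the temperature unchanged and doubling the blood
#' volume halves the increment.
#'
#' @param state an [arterial_state()].
#' @param q_therm perfusion heat gain, W.
#' @param dt time step, s.
#' @return the updated `arterial_state`.
#' @export
update_arterial <- function(state, q_therm, dt) {
  stopifnot(inherits(state, "arterial_state"), dt > 0)
  if (state$V_b <= 0) stop("blood volume must be positive")
  q_skin <- state$hA_skin * (state$T_a - state$T_env)
  q_tail <- state$hA_tail * (state$T_a - state$T_env)
  d_ta <- (state$q_m + q_therm - q_skin - q_tail) * dt /
    (state$rho_b * state$c_b * state$V_b)
  state$T_a <- state$T_a + d_ta
  state
}

#' One-dimensional Pennes bioheat slab model
#'
#' Solves \eqn{\rho_t c_t \partial_t T - k_t \partial_x^2 T =
#' -\rho_b w_b c_b (T - T_a)} on a tissue slab with implicit
#' (unconditionally stable) time stepping. The left face carries the heated
#' boundary (fixed temperature, e.g. the 43 degC perfusate); the right face
#' is a fixed temperature, a constant outward heat flux (e.g. the 600
#' W/m\eqn{^2} open-surface loss), or insulated. The arterial temperature is
#' either held fixed or updated each step through [update_arterial()], with
#' the perfusion heat exchange integrated over the slab and scaled by the
#' `area_m2` cross-section.
#'
#' @param props one-row tibble of tissue properties (a row of
#'   [thermal_properties()]), or an organ name.
#' @param length_m slab thickness, m.
#' @param n number of cells.
#' @param t_f horizon, s; `dt` time step, s.
#' @param T_init initial tissue temperature, degC.
#' @param left fixed temperature at the heated face, degC.
#' @param right list describing the far boundary: `list(type = "dirichlet",
#'   value = 37)`, `list(type = "flux", q = 600)` (outward W/m\eqn{^2}) or
#'   `list(type = "insulated")`.
#' @param arterial `NULL` for a fixed 37 degC arterial pool, a number for a
#'   fixed pool at that temperature, or an [arterial_state()] to enable the
#'   lumped feedback.
#' @param area_m2 slab cross-section used to scale the perfusion heat
#'   exchange fed back to the arterial pool (default 1e-3 m\eqn{^2}, a
#'   rat-scale heated tissue patch).
#' @param blood blood properties.
#' @return An object of class `bioheat_fit` with the temperature field
#'   (`position_m` x snapshots), the arterial trajectory and a per-step
#'   energy-balance record. [tidy()] returns position-time temperatures.
#' @export
#' @examples
#' fit <- bioheat_slab("liver", length_m = 0.02, n = 100, t_f = 600)
#' tail(tidy(fit))
bioheat_slab <- function(props = "liver", length_m = 0.02, n = 200,
                         t_f = 1800, dt = 1, T_init = 37, left = 43,
                         right = list(type = "dirichlet", value = 37),
                         arterial = NULL, area_m2 = 1e-3,
                         blood = blood_properties()) {
  stopifnot(dt > 0, n >= 3L, length_m > 0)
  if (is.character(props)) {
    tp <- thermal_properties()
    props <- tp[tp$organ == props, ]
    if (nrow(props) != 1L) stop("unknown organ")
  }
  h <- length_m / n
  x <- (seq_len(n) - 0.5) * h
  rho_c <- props$rho_t * props$c_t
  k <- props$k_t
  sink <- blood$rho_b * props$w_b * blood$c_b # W/m^3/K

  coupled <- inherits(arterial, "arterial_state")
  t_a <- if (coupled) arterial$T_a else if (is.numeric(arterial)) arterial else 37

  # implicit system in flux form (unit cross-section, cell volume h):
  # (h rho c/dt + h sink) T + face conductances; conductance k/h in W/m^2/K
  gi <- k / h
  main <- rep(h * (rho_c / dt + sink), n)
  upper <- rep(-gi, n - 1L)
  main[2:(n - 1L)] <- main[2:(n - 1L)] + 2 * gi
  main[1L] <- main[1L] + gi + 2 * k / h # Dirichlet left at half-cell
  g_left <- 2 * k / h
  rtype <- right$type %||% "dirichlet"
  g_right <- 0
  if (rtype == "dirichlet") {
    main[n] <- main[n] + gi + 2 * k / h
    g_right <- 2 * k / h
  } else {
    main[n] <- main[n] + gi
  }
  a_sys <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                              diagonals = list(upper, main, upper),
                              symmetric = FALSE)
  lu <- Matrix::lu(a_sys)

  temp <- rep(T_init, n)
  nsteps <- ceiling(t_f / dt - 1e-9)
  snap_every <- max(1L, floor(nsteps / 50))
  snaps <- list(temp)
  snap_times <- 0
  ta_series <- numeric(nsteps + 1L)
  ta_series[1L] <- t_a
  ebal <- numeric(nsteps)

  for (s in seq_len(nsteps)) {
    rhs <- h * (rho_c / dt * temp + sink * t_a)
    rhs[1L] <- rhs[1L] + g_left * left
    if (rtype == "dirichlet") rhs[n] <- rhs[n] + g_right * right$value
    if (rtype == "flux") rhs[n] <- rhs[n] - (right$q %||% 600)
    new <- as.numeric(Matrix::solve(lu, rhs))
    # discrete energy balance per step (W/m^2 of slab cross-section)
    flux_in <- g_left * (left - new[1L])
    flux_out <- switch(rtype,
      dirichlet = g_right * (new[n] - right$value),
      flux = (right$q %||% 600),
      insulated = 0
    )
    sink_tot <- sum(sink * (new - t_a)) * h
    stored <- sum(rho_c * (new - temp)) * h / dt
    ebal[s] <- flux_in - flux_out - sink_tot - stored
    temp <- new
    q_therm <- sink_tot * area_m2 # tissue heat removed enters the blood pool
    if (coupled) {
      arterial <- update_arterial(arterial, q_therm, dt)
      t_a <- arterial$T_a
    }
    ta_series[s + 1L] <- t_a
    if (s %% snap_every == 0L || s == nsteps) {
      snaps[[length(snaps) + 1L]] <- temp
      snap_times <- c(snap_times, s * dt)
    }
  }

  structure(
    list(position_m = x, snapshots = snaps, snap_times = snap_times,
         T_a = ta_series, times = c(0, seq_len(nsteps) * dt),
         energy_balance_W_m2 = ebal, props = props, length_m = length_m,
         dt = dt, t_f = t_f, sink_W_m3_K = sink, left = left, right = right),
    class = "bioheat_fit"
  )
}

#' @export
print.bioheat_fit <- function(x, ...) {
  cat("<bioheat_fit> ", length(x$position_m), " cells, t_f = ", x$t_f,
      " s, final T range ", paste(signif(range(tail(x$snapshots, 1L)[[1L]]), 4),
                                  collapse = " - "), " degC\n", sep = "")
  invisible(x)
}

#' @describeIn bioheat_slab temperature field in tidy form.
#' @param x a `bioheat_fit`.
#' @param ... unused.
#' @export
tidy.bioheat_fit <- function(x, ...) {
  tibble::tibble(
    time_s = rep(x$snap_times, each = length(x$position_m)),
    position_m = rep(x$position_m, times = length(x$snap_times)),
    temp_c = unlist(x$snapshots, use.names = FALSE)
  )
}
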