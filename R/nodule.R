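#' Geometry of a half-embedded peritoneal tumour nodule
#'
#' An axisymmetric (r, z) domain describing a spherical nodule of diameter
#' `tumor_diameter` centred on the host-tissue surface plane: the upper
#' hemisphere is exposed to the perfusate, the lower hemisphere is embedded
#' in host tissue. The host block extends `host_extent` radially and `depth`
#' axially below the surface, i.e. with the defaults the host region is five
#' times the size of the tumour (a 10 mm wide and 5 mm deep block around a
#' 2 mm nodule). Setting `tumor_diameter = 0` gives a pure host slab whose
#' whole upper surface is exposed; this degenerate configuration is used for
#' verification against one-dimensional closed forms.
#'
#' @param tumor_diameter nodule diameter, m (default 2 mm, the residual-
#'   disease scale after cytoreductive surgery).
#' @param host_extent radial half-width of the host block, m.
#' @param depth axial depth of the host block below the surface plane, m.
#' @param mesh_spacing uniform cell size, m (default 0.05 mm, resolving the
#'   tumour with 40 cells across its diameter).
#' @return An object of class `nodule_geometry`.
#' @export
#' @examples
#' nodule_geometry()
nodule_geometry <- function(tumor_diameter = 2e-3,
                            host_extent = 2.5 * max(tumor_diameter, 2e-3),
                            depth = host_extent,
                            mesh_spacing = 5e-5) {
  stopifnot(tumor_diameter >= 0, host_extent > 0, depth > 0, mesh_spacing > 0)
  if (tumor_diameter > 0 && tumor_diameter / mesh_spacing < 10) {
    warning("mesh resolves the tumour with fewer than 10 cells across the ",
            "diameter; results will be under-resolved")
  }
  structure(
    list(tumor_diameter = tumor_diameter, host_extent = host_extent,
         depth = depth, mesh_spacing = mesh_spacing),
    class = "nodule_geometry"
  )
}

# Discretize the axisymmetric domain into grid cells and classify regions.
# Rows run from the top of the domain (exposed pole) downward.
build_nodule_grid <- function(geom) {
  h <- geom$mesh_spacing
  r_t <- geom$tumor_diameter / 2
  nr <- max(1L, round(geom$host_extent / h))
  z_top <- r_t
  nz <- round((z_top + geom$depth) / h)
  r_c <- (seq_len(nr) - 0.5) * h
  z_c <- z_top - (seq_len(nz) - 0.5) * h
  rr <- matrix(r_c, nz, nr, byrow = TRUE)
  zz <- matrix(z_c, nz, nr)
  dist <- sqrt(rr^2 + zz^2)
  region <- matrix("host", nz, nr)
  region[dist <= r_t] <- "tumor"
  region[zz > 0 & dist > r_t] <- "cavity"
  list(h = h, nr = nr, nz = nz, r_c = r_c, z_c = z_c, rr = rr, zz = zz,
       region = region, r_t = r_t)
}

#' Solve drug transport in a half-embedded tumour nodule
#'
#' Advances the diffusion-reaction equation
#' \deqn{\partial_t C - \nabla\cdot(D\nabla C) = -(\beta +
#'   P_c \tfrac{S}{V} \tfrac{Pe_v}{e^{Pe_v}-1} y(T))\, C}
#' on the axisymmetric nodule + host domain with implicit (backward Euler)
#' time stepping. The perfusate concentration of the boundary series is
#' imposed as a Dirichlet condition on every surface in contact with the
#' cavity (the exposed tumour hemisphere and the surrounding host surface
#' plane); flux continuity holds at the tumour-host interface through
#' harmonic averaging of the diffusivity, and the far host boundaries are
#' zero-gradient. The tissue temperature is uniform at the organ-surface
#' plateau of the boundary series and enters through the washout factor
#' y(T). The scheme is conservative: the discrete balance
#' (boundary influx - sink losses - stored mass) is tracked and reported.
#'
#' @param boundary a boundary series from [generate_boundary()] (columns
#'   `time_s`, `conc_mol_m3`, `temp_c`), or a list with elements `conc`
#'   (function of time, mol/m\eqn{^3}) and `temp_c`.
#' @param tumor_params,host_params [transport_params()] for the two regions.
#'   Host parameters are never modified by scenario transforms.
#' @param geometry a [nodule_geometry()].
#' @param t_f final time, s; defaults to the boundary-series horizon.
#' @param dt time step, s. The implicit scheme is unconditionally stable;
#'   the default 0.5 s resolves the fastest washout time scale.
#' @param snapshot_every cadence (in steps) at which axis concentration
#'   profiles are stored; the final profile is always stored.
#' @param host_surface `"sealed"` (default): the perfusate Dirichlet
#'   condition applies to the exposed tumour hemisphere only and the host
#'   surface plane is drug-impermeable, as in the model's boundary-condition
#'   set; `"exposed"`: the host surface plane also carries the perfusate
#'   concentration. In a pure host slab (`tumor_diameter = 0`) the whole
#'   upper surface is always exposed.
#' @return An object of class `nodule_fit` with the mean-concentration and
#'   sink time series, the final concentration field, stored axis profiles,
#'   and the discrete mass-balance record. Use [tidy()] for the time series,
#'   [glance()] for a one-row summary, [axis_profile()] for depth profiles.
#' @export
#' @examples
#' b <- generate_boundary("intestine", 1)
#' fit <- solve_nodule(b, geometry = nodule_geometry(mesh_spacing = 2e-4),
#'                     t_f = 300, dt = 2)
#' glance(fit)
solve_nodule <- function(boundary,
                         tumor_params = transport_params("tumor"),
                         host_params = transport_params("normal"),
                         geometry = nodule_geometry(),
                         t_f = NULL, dt = 0.5,
                         snapshot_every = 120L,
                         host_surface = c("sealed", "exposed")) {
  stopifnot(dt > 0)
  host_surface <- match.arg(host_surface)
  if (is.data.frame(boundary)) {
    stopifnot(all(c("time_s", "conc_mol_m3", "temp_c") %in% names(boundary)))
    temp_c <- unique(boundary$temp_c)
    if (length(temp_c) != 1L) {
      stop("boundary temperature must be a constant plateau")
    }
    horizon <- max(boundary$time_s)
    conc_fun <- approxfun(boundary$time_s, boundary$conc_mol_m3, rule = 2)
  } else {
    stopifnot(is.function(boundary$conc), is.numeric(boundary$temp_c))
    temp_c <- boundary$temp_c
    horizon <- Inf
    conc_fun <- boundary$conc
  }
  t_f <- t_f %||% horizon
  if (!is.finite(t_f)) stop("t_f must be supplied with a functional boundary")
  if (t_f > horizon + 1e-9) {
    stop("boundary series (", horizon, " s) is shorter than t_f (", t_f, " s)")
  }

  g <- build_nodule_grid(geometry)
  act <- g$region != "cavity"
  n <- sum(act)
  if (n == 0L) stop("empty computational domain")
  idx <- matrix(0L, g$nz, g$nr)
  idx[act] <- seq_len(n)

  is_tum <- g$region == "tumor"
  d_cell <- matrix(host_params$D, g$nz, g$nr)
  d_cell[is_tum] <- tumor_params$D
  kv_t <- vascular_rate(tumor_params, temp_c)
  kv_h <- vascular_rate(host_params, temp_c)
  kvas <- matrix(kv_h, g$nz, g$nr)
  kvas[is_tum] <- kv_t
  bet <- matrix(host_params$beta, g$nz, g$nr)
  bet[is_tum] <- tumor_params$beta

  h <- g$h
  vol <- 2 * pi * g$rr * h^2 # cell volumes

  # --- assemble symmetric flux matrix ----------------------------------
  acc <- function(ids, val) {
    out <- numeric(n)
    if (length(ids)) {
      s <- rowsum(val, ids)
      out[as.integer(rownames(s))] <- s[, 1L]
    }
    out
  }
  off_i <- integer(0); off_j <- integer(0); off_g <- numeric(0)
  dir_ids <- integer(0); dir_g <- numeric(0)
  # Dirichlet faces on the stair-stepped hemisphere use the exact distance
  # from the cell centre to the spherical surface along the face normal
  # (clamped to [0.05 h, h]); plane surfaces use the half-cell distance.
  clamp_d <- function(d) pmax(pmin(d, h), 0.05 * h)
  r_t <- g$r_t

  if (g$nr > 1L) {
    # radial faces between columns j and j+1, at radius j*h
    jl <- idx[, -g$nr, drop = FALSE]; jr <- idx[, -1L, drop = FALSE]
    rface <- matrix((seq_len(g$nr - 1L)) * h, g$nz, g$nr - 1L, byrow = TRUE)
    area <- 2 * pi * rface * h
    dl <- d_cell[, -g$nr, drop = FALSE]; dr <- d_cell[, -1L, drop = FALSE]
    gface <- area * (2 * dl * dr / (dl + dr)) / h
    both <- jl > 0L & jr > 0L
    off_i <- c(off_i, jl[both]); off_j <- c(off_j, jr[both])
    off_g <- c(off_g, gface[both])
    # radial Dirichlet faces against cavity cells (stair-stepped hemisphere)
    lc <- jl > 0L & jr == 0L
    if (any(lc)) {
      zz_l <- g$zz[, -g$nr, drop = FALSE]
      rr_l <- g$rr[, -g$nr, drop = FALSE]
      tum_l <- is_tum[, -g$nr, drop = FALSE]
      r_b <- sqrt(pmax(r_t^2 - zz_l^2, 0))
      d_l <- matrix(h / 2, g$nz, g$nr - 1L)
      d_l[tum_l] <- clamp_d(r_b - rr_l)[tum_l]
      dir_ids <- c(dir_ids, jl[lc]); dir_g <- c(dir_g, (area * dl / d_l)[lc])
    }
    rc <- jr > 0L & jl == 0L
    dir_ids <- c(dir_ids, jr[rc]); dir_g <- c(dir_g, (area * dr / (h / 2))[rc])
  }
  # axial faces between rows i and i+1
  iu <- idx[-g$nz, , drop = FALSE]; id <- idx[-1L, , drop = FALSE]
  area_ax <- matrix(2 * pi * g$r_c * h, g$nz - 1L, g$nr, byrow = TRUE)
  du <- d_cell[-g$nz, , drop = FALSE]; dd <- d_cell[-1L, , drop = FALSE]
  gface <- area_ax * (2 * du * dd / (du + dd)) / h
  both <- iu > 0L & id > 0L
  off_i <- c(off_i, iu[both]); off_j <- c(off_j, id[both])
  off_g <- c(off_g, gface[both])
  # axial Dirichlet faces: active cell below a cavity cell
  uc <- id > 0L & iu == 0L
  if (any(uc)) {
    zz_d <- g$zz[-1L, , drop = FALSE]
    rr_d <- g$rr[-1L, , drop = FALSE]
    tum_d <- is_tum[-1L, , drop = FALSE]
    z_b <- sqrt(pmax(r_t^2 - rr_d^2, 0))
    d_d <- matrix(h / 2, g$nz - 1L, g$nr)
    d_d[tum_d] <- clamp_d(z_b - zz_d)[tum_d]
    dir_ids <- c(dir_ids, id[uc]); dir_g <- c(dir_g, (area_ax * dd / d_d)[uc])
  }
  # top boundary row: active cells exposed directly at the domain top
  top <- idx[1L, ]
  topact <- top > 0L
  if (any(topact)) {
    a_top <- 2 * pi * g$r_c[topact] * h
    d_t <- rep(h / 2, sum(topact))
    if (r_t > 0) {
      z_b <- sqrt(pmax(r_t^2 - g$r_c[topact]^2, 0))
      tum_t <- is_tum[1L, topact]
      d_t[tum_t] <- clamp_d(z_b - g$z_c[1L])[tum_t]
    }
    dir_ids <- c(dir_ids, top[topact])
    dir_g <- c(dir_g, a_top * d_cell[1L, topact] / d_t)
  }

  vols <- vol[act]
  ksink <- (bet + kvas)[act]
  # sealed host surface: only tumour cells receive the Dirichlet condition
  if (host_surface == "sealed" && geometry$tumor_diameter > 0) {
    keep <- is_tum[act][dir_ids]
    dir_ids <- dir_ids[keep]
    dir_g <- dir_g[keep]
  }
  gdir <- acc(dir_ids, dir_g)
  diag_vals <- vols / dt + vols * ksink +
    acc(off_i, off_g) + acc(off_j, off_g) + gdir
  a_sys <- Matrix::sparseMatrix(
    i = c(seq_len(n), off_i, off_j),
    j = c(seq_len(n), off_j, off_i),
    x = c(diag_vals, -off_g, -off_g),
    dims = c(n, n)
  )
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(a_sys), LDL = FALSE)

  # --- bookkeeping vectors ---------------------------------------------
  tum <- is_tum[act]
  hst <- !tum
  v_tum <- vols[tum]; v_hst <- vols[hst]
  vt_total <- sum(v_tum)
  kv_cell <- kvas[act]
  # axis column (j = 1) ordered top to bottom; depth measured from the
  # exposed pole of the tumour (the top of the domain)
  axis_rows <- which(idx[, 1L] > 0L)
  axis_ids <- idx[axis_rows, 1L]
  axis_depth <- (g$r_t - g$z_c[axis_rows])
  axis_region <- g$region[cbind(axis_rows, 1L)]

  nsteps <- ceiling(t_f / dt - 1e-9)
  times <- c(0, seq_len(nsteps) * dt)
  conc <- numeric(n)
  mean_tumor <- numeric(nsteps + 1L)
  mean_host <- numeric(nsteps + 1L)
  sv_tumor <- numeric(nsteps + 1L)
  sv_host <- numeric(nsteps + 1L)
  influx <- numeric(nsteps + 1L)
  cum_in <- 0; cum_sink <- 0
  snaps <- list()
  snap_times <- numeric(0)

  for (s in seq_len(nsteps)) {
    tb <- times[s + 1L]
    cb <- conc_fun(tb)
    b <- vols * conc / dt + gdir * cb
    conc <- as.numeric(Matrix::solve(ch, b, system = "A"))
    if (vt_total > 0) mean_tumor[s + 1L] <- sum(v_tum * conc[tum]) / vt_total
    mean_host[s + 1L] <- sum(v_hst * conc[hst]) / sum(v_hst)
    sv_tumor[s + 1L] <- sum(v_tum * kv_cell[tum] * conc[tum])
    sv_host[s + 1L] <- sum(v_hst * kv_cell[hst] * conc[hst])
    influx[s + 1L] <- sum(gdir * (cb - conc))
    cum_in <- cum_in + influx[s + 1L] * dt
    cum_sink <- cum_sink + sum(vols * ksink * conc) * dt
    if (s %% snapshot_every == 0L || s == nsteps) {
      snaps[[length(snaps) + 1L]] <- conc[axis_ids]
      snap_times <- c(snap_times, tb)
    }
  }
  mass <- sum(vols * conc)
  mb_rel <- (cum_in - cum_sink - mass) / max(cum_in, .Machine$double.eps)

  axis_snapshots <- tibble::tibble(
    time_s = rep(snap_times, each = length(axis_ids)),
    depth_m = rep(axis_depth, times = length(snap_times)),
    region = rep(axis_region, times = length(snap_times)),
    conc_mol_m3 = unlist(snaps, use.names = FALSE)
  )
  field <- tibble::tibble(
    r_m = g$rr[act], z_m = g$zz[act],
    region = g$region[act], volume_m3 = vols, conc_mol_m3 = conc
  )

  structure(
    list(
      times = times, mean_tumor = mean_tumor, mean_host = mean_host,
      sv_tumor = sv_tumor, sv_host = sv_host, influx = influx,
      axis_snapshots = axis_snapshots, field = field,
      mass_balance = list(rel_error = mb_rel, cum_influx = cum_in,
                          cum_sink = cum_sink, stored = mass),
      boundary_conc = vapply(times, conc_fun, numeric(1L)),
      geometry = geometry, dt = dt, t_f = t_f, temp_c = temp_c,
      n_cells = n, tumor_volume_m3 = vt_total,
      tumor_params = tumor_params, host_params = host_params
    ),
    class = "nodule_fit"
  )
}

#' @export
print.nodule_fit <- function(x, ...) {
  cat("<nodule_fit> ", x$n_cells, " cells, t_f = ", x$t_f, " s, T = ",
      x$temp_c, " degC\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' @describeIn solve_nodule time series of mean concentrations and sinks.
#' @param x a `nodule_fit`.
#' @param ... unused.
#' @export
tidy.nodule_fit <- function(x, ...) {
  tibble::tibble(
    time_s = x$times,
    mean_tumor_mol_m3 = x$mean_tumor,
    mean_host_mol_m3 = x$mean_host,
    sv_tumor_mol_s = x$sv_tumor,
    sv_host_mol_s = x$sv_host,
    influx_mol_s = x$influx
  )
}

#' @describeIn solve_nodule one-row summary (tumour AUC, final mean
#'   concentration, mass-balance error).
#' @export
glance.nodule_fit <- function(x, ...) {
  tibble::tibble(
    tumor_auc_mol_s_m3 = tumor_auc(x),
    mean_tumor_final_mol_m3 = tail(x$mean_tumor, 1L),
    mass_balance_rel_error = x$mass_balance$rel_error,
    n_cells = x$n_cells,
    t_f = x$t_f,
    dt = x$dt,
    temp_c = x$temp_c
  )
}

#' Concentration-depth profile along the symmetry axis
#'
#' Depth is measured from the exposed pole of the nodule into the tissue;
#' the tumour occupies depths up to one diameter, host tissue lies beyond.
#'
#' @param fit a [solve_nodule()] result.
#' @param time snapshot time, s, or `"final"`.
#' @return A tibble with `depth_m`, `region`, `conc_mol_m3`.
#' @export
axis_profile <- function(fit, time = "final") {
  stopifnot(inherits(fit, "nodule_fit"))
  snaps <- fit$axis_snapshots
  tt <- if (identical(time, "final")) max(snaps$time_s) else {
    avail <- unique(snaps$time_s)
    avail[which.min(abs(avail - time))]
  }
  dplyr::filter(snaps, .data$time_s == tt)[, c("depth_m", "region", "conc_mol_m3")]
}
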