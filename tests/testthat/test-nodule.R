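test_that("zero boundary and zero initial condition give an identically zero field", {
  fit <- coarse_fit(boundary = const_boundary(0), t_f = 100, dt = 10)
  expect_equal(max(abs(fit$field$conc_mol_m3)), 0)
  expect_equal(max(abs(fit$mean_tumor)), 0)
})

test_that("early-time axial diffusion matches the erfc closed form", {
  # pure-diffusion slab (no tumour, no sinks), whole surface at constant C0:
  # C(x, t) = C0 erfc(x / (2 sqrt(D t)))
  c0 <- 0.16
  d <- 3e-9
  geo <- suppressWarnings(nodule_geometry(tumor_diameter = 0,
                                          host_extent = 2.5e-5, depth = 2e-3,
                                          mesh_spacing = 2.5e-5))
  fit <- solve_nodule(const_boundary(160, 37),
                      tumor_params = transport_params("tumor", P_c = 0, beta = 0),
                      host_params = transport_params("normal", P_c = 0, beta = 0),
                      geometry = geo, t_f = 60, dt = 0.05,
                      snapshot_every = 1200L)
  p <- axis_profile(fit)
  sel <- p$depth_m < 3e-4
  exact <- c0 * pracma::erfc(p$depth_m[sel] / (2 * sqrt(d * 60)))
  expect_lt(max(abs(p$conc_mol_m3[sel] - exact) / exact), 0.02)
})

test_that("the solver is linear in the boundary concentration", {
  f1 <- coarse_fit(boundary = rising_boundary(160), t_f = 200, dt = 10)
  f2 <- coarse_fit(boundary = rising_boundary(320), t_f = 200, dt = 10)
  expect_equal(f2$field$conc_mol_m3, 2 * f1$field$conc_mol_m3,
               tolerance = 1e-10)
  expect_equal(f2$mean_tumor, 2 * f1$mean_tumor, tolerance = 1e-10)
})

test_that("tumour AUC moves monotonically with the transport parameters", {
  base <- transport_params("tumor")
  auc_with <- function(...) {
    tumor_auc(coarse_fit(transport_params("tumor", ...), t_f = 300, dt = 10))
  }
  auc0 <- tumor_auc(coarse_fit(base, t_f = 300, dt = 10))
  expect_lt(auc_with(P_c = base$P_c * 2), auc0)       # more washout
  expect_gt(auc_with(P_c = base$P_c * 0.5), auc0)
  expect_lt(auc_with(beta = base$beta * 10), auc0)     # more elimination
  expect_lt(auc_with(S_over_V = base$S_over_V * 2), auc0)
  expect_gt(auc_with(D = base$D * 2), auc0)            # easier penetration
})

test_that("heating increases tumour exposure through reduced washout", {
  a37 <- tumor_auc(coarse_fit(boundary = rising_boundary(160, temp_c = 37),
                              t_f = 300, dt = 10))
  a43 <- tumor_auc(coarse_fit(boundary = rising_boundary(160, temp_c = 43),
                              t_f = 300, dt = 10))
  expect_gt(a43, a37)
})

test_that("discrete mass balance closes", {
  fit <- coarse_fit(t_f = 300, dt = 5)
  expect_lt(abs(fit$mass_balance$rel_error), 0.005)
  # and essentially to machine precision for the conservative scheme
  expect_lt(abs(fit$mass_balance$rel_error), 1e-10)
})

test_that("halving the mesh changes tumour AUC by less than 1%", {
  bfun <- rising_boundary()
  a1 <- tumor_auc(solve_nodule(bfun, geometry = coarse_geom(mesh = 5e-5),
                               t_f = 600, dt = 2, snapshot_every = 1000L))
  a2 <- tumor_auc(solve_nodule(bfun, geometry = coarse_geom(mesh = 2.5e-5),
                               t_f = 600, dt = 2, snapshot_every = 1000L))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("production solver agrees with a forward-Euler brute force in 1D", {
  # 10-node column, uniform parameters, constant surface concentration
  h <- 1e-4
  n <- 10L
  d <- 3e-9
  k <- 0.02 # 1/s, lumped sink
  c0 <- 0.16
  dt <- 0.001
  t_f <- 5
  # independent explicit integration of the same finite-volume system
  conc <- numeric(n)
  g <- d / h # face conductance per unit area / h
  for (s in seq_len(t_f / dt)) {
    flux <- numeric(n)
    flux[1L] <- 2 * g * (c0 - conc[1L]) - g * (conc[1L] - conc[2L])
    for (i in 2:(n - 1L)) {
      flux[i] <- g * (conc[i - 1L] - conc[i]) - g * (conc[i] - conc[i + 1L])
    }
    flux[n] <- g * (conc[n - 1L] - conc[n])
    conc <- conc + dt * (flux / h - k * conc)
  }
  # production path: slab mode, sink expressed through beta only
  geo <- suppressWarnings(nodule_geometry(tumor_diameter = 0, host_extent = h,
                                          depth = n * h, mesh_spacing = h))
  fit <- solve_nodule(const_boundary(160, 37),
                      host_params = transport_params("normal", P_c = 0,
                                                     beta = k, D = d),
                      geometry = geo, t_f = t_f, dt = dt,
                      snapshot_every = 10000L)
  prod <- axis_profile(fit)$conc_mol_m3
  expect_equal(length(prod), n)
  expect_lt(max(abs(prod - conc) / max(conc)), 1e-3)
})

test_that("host tissue adjacent to a high-hindrance tumour carries more drug than the tumour interior", {
  params <- apply_stiffness(transport_params("tumor"), "high")
  fit <- coarse_fit(params, t_f = 900, dt = 10, mesh = 1e-4)
  p <- axis_profile(fit)
  host_adjacent <- max(p$conc_mol_m3[p$region == "host"])
  tum <- p[p$region == "tumor", ]
  interior_min <- min(tum$conc_mol_m3[tum$depth_m > 1e-3])
  expect_gt(host_adjacent, interior_min)
})

test_that("solver rejects inconsistent inputs", {
  b <- generate_boundary("liver", 1, schedule = perfusion_schedule(t_f = 100))
  expect_error(solve_nodule(b, geometry = coarse_geom(), t_f = 500),
               "shorter than")
  expect_error(solve_nodule(rising_boundary(), geometry = coarse_geom(),
                            t_f = 100, dt = -1), "dt > 0")
  bb <- generate_boundary("liver", 1)
  bb$temp_c <- seq_len(nrow(bb)) # non-constant plateau
  expect_error(solve_nodule(bb, geometry = coarse_geom()), "plateau")
})
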