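# shared fixtures: coarse geometries and boundary functions used across tests

coarse_geom <- function(mesh = 2e-4, extent = 2.5e-3) {
  suppressWarnings(nodule_geometry(host_extent = extent, depth = extent,
                                   mesh_spacing = mesh))
}

# constant-plateau boundary as a functional series
const_boundary <- function(c0_uM = 160, temp_c = 40.1) {
  list(conc = function(t) rep(uM_to_mol_m3(c0_uM), length(t)), temp_c = temp_c)
}

rising_boundary <- function(c0_uM = 160, temp_c = 40.1, tau = 180) {
  list(conc = function(t) uM_to_mol_m3(c0_uM) * (1 - exp(-t / tau)),
       temp_c = temp_c)
}

coarse_fit <- function(tumor_params = transport_params("tumor"),
                       boundary = rising_boundary(), t_f = 300, dt = 5,
                       mesh = 2e-4, ...) {
  solve_nodule(boundary, tumor_params = tumor_params,
               geometry = coarse_geom(mesh), t_f = t_f, dt = dt,
               snapshot_every = 1000L, ...)
}

# minimal hand-built object for the pure time-series metrics
fake_fit <- function(times, mean_tumor) {
  structure(
    list(times = times, mean_tumor = mean_tumor, tumor_volume_m3 = 1,
         geometry = list(tumor_diameter = 2e-3)),
    class = "nodule_fit"
  )
}
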