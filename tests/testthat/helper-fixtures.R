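# Shared fixtures: built in code, cached across test files so the full
# default-schedule runs are executed once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg_fun) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- run_simulation(cfg_fun())
  .sim_cache[[key]]
}

default_ukak_run <- function() cached_sim("ukak", function() {
  default_config("UKAK")
})

default_uka_run <- function() cached_sim("uka", function() {
  default_config("UKA")
})

refined_ukak_run <- function() cached_sim("ukak_fine_steps", function() {
  default_config("UKAK",
                 overrides = list(wear = list(n_steps = 20L,
                                              cycles_per_step = 2.5e5)))
})

# Fully conforming pair with identical square footprints: uniform pressure.
conforming_pair <- function(side = 20, radius = 1e6, thickness = 8,
                            resolution = 1) {
  spec <- implant_spec(femoral_ml_width = side, femoral_ap_length = side,
                       insert_ml = side, insert_ap = side,
                       insert_thickness = thickness,
                       femoral_sagittal_radius = radius,
                       femoral_coronal_radius = radius,
                       insert_sagittal_radius = radius,
                       insert_coronal_radius = radius)
  compartment_geometry(make_femoral_surface(spec, resolution),
                       make_insert_surface(spec, resolution),
                       layer_thickness = thickness,
                       label = "medial_implant", center_z = 0)
}

# Spherical femoral condyle (R = 28 mm) over a flat bearing layer.
sphere_on_flat <- function(resolution = 4, radius = 28) {
  spec <- implant_spec(femoral_sagittal_radius = radius,
                       femoral_coronal_radius = radius,
                       insert_sagittal_radius = 1e9,
                       insert_coronal_radius = 1e9)
  compartment_geometry(make_femoral_surface(spec, resolution),
                       make_insert_surface(spec, resolution),
                       layer_thickness = 8,
                       label = "medial_implant", center_z = 0)
}

pe_foundation <- function() foundation_params(940, 0.46, 8)

# Small flat bearing surface of given node count and spacing, as a
# compartment under the default femoral component.
flat_toy_compartment <- function(n = 10, dx = 1, height = 8) {
  ax <- seq(-(n - 1) / 2 * dx, (n - 1) / 2 * dx, by = dx)
  tib <- surface_grid(ax, ax, matrix(height, n, n))
  spec <- implant_spec()
  compartment_geometry(make_femoral_surface(spec, 1 / dx), tib,
                       layer_thickness = height,
                       label = "medial_implant", center_z = 0)
}
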