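make_mirror_joint <- function() {
  spec <- implant_spec()
  med <- make_medial_compartment(spec, 1, center_z = 25)
  lat <- compartment_geometry(make_femoral_surface(spec, 1),
                              make_insert_surface(spec, 1),
                              layer_thickness = 8,
                              label = "lateral_cartilage", center_z = -25)
  list(medial = med, lateral = lat)
}

test_that("mirror-symmetric compartments with a centred load split evenly", {
  j <- make_mirror_joint()
  cfg <- joint_config(femoral_load_offset = 0, vv_restraint_stiffness = 0)
  eq <- solve_joint_equilibrium(j$medial, j$lateral, 2000, cfg,
                                pe_foundation(), pe_foundation())
  expect_equal(eq$split$medial_fraction, 0.5, tolerance = 1e-12)
  expect_equal(eq$split$vv_tilt, 0, tolerance = 1e-12)
  expect_equal(eq$split$f_medial + eq$split$f_lateral, 2000,
               tolerance = 1e-6 * 2000)
})

test_that("a vanishing lateral foundation routes the load medially", {
  j <- make_mirror_joint()
  cfg <- joint_config()
  soft <- foundation_params(1e-6, 0.46, 8)
  eq <- solve_joint_equilibrium(j$medial, j$lateral, 2600, cfg,
                                pe_foundation(), soft)
  expect_gt(eq$split$medial_fraction, 0.999)
  expect_lt(eq$split$vv_tilt, 0)   # tips toward the unsupported side
  # without the ligamentous restraint the moment cannot balance: the
  # passive tilt limit is engaged and the residual moment reported
  free <- joint_config(vv_restraint_stiffness = 0)
  eqf <- solve_joint_equilibrium(j$medial, j$lateral, 2600, free,
                                 pe_foundation(), soft)
  expect_gt(eqf$split$medial_fraction, 0.999)
  expect_equal(abs(eqf$split$vv_tilt), free$vv_tilt_limit, tolerance = 1e-9)
  expect_gt(abs(eqf$split$moment_residual), 0.1)
})

test_that("default whole-joint split at the first peak is medially dominant", {
  h <- default_ukak_run()$history
  frac0 <- h$medial_fraction_peak1[1]
  expect_gt(frac0, 0.55)
  expect_lt(frac0, 0.85)
  expect_gt(frac0, 0.5)
})

test_that("force and moment residual contracts hold over a full cycle", {
  res <- default_ukak_run()
  cyc <- res$first_cycle
  expect_true(all(abs(cyc$f_medial_N + cyc$f_lateral_N - cyc$axial_N)
                  <= pmax(1e-3, 0.001 * cyc$axial_N)))
  expect_true(all(cyc$medial_fraction >= 0 & cyc$medial_fraction <= 1,
                  na.rm = TRUE))
})

test_that("medial fraction responds monotonically to lateral layer stiffness", {
  cfg <- default_config("UKAK")
  scen <- build_scenario(cfg)
  i0 <- which.min(abs(scen$waveforms$t - 0.13))
  frac <- vapply(c(0.5, 1, 2), function(scale) {
    fl <- scen$foundation_lateral
    fl$youngs_modulus <- fl$youngs_modulus * scale
    solve_joint_equilibrium(scen$medial, scen$lateral, 2600, scen$joint,
                            scen$foundation_medial, fl,
                            kin_medial = scen$kin_list[[i0]]
                            )$split$medial_fraction
  }, numeric(1L))
  expect_true(all(diff(frac) < 0))
})

test_that("confined-compression von Mises surrogate matches its closed form", {
  expect_equal(cartilage_von_mises(7, 0), 7)
  expect_equal(cartilage_von_mises(10, 0.475), 10 * (1 - 0.95) / 0.525,
               tolerance = 1e-12)
  expect_equal(round(cartilage_von_mises(10, 0.475), 4), 0.9524)
  expect_lt(cartilage_von_mises(10, 0.4999), 0.01)
  p <- c(0.5, 2, 8)
  expect_true(all(cartilage_von_mises(p, 0.3) <= p))
  expect_error(cartilage_von_mises(1, 0.5), "0.5")
})

test_that("lateral stress trajectory peaks in stance and rises with wear", {
  res <- default_ukak_run()
  first <- res$first_cycle
  i_max <- which.max(first$lat_peak_vm_MPa)
  expect_lt(first$t[i_max], 0.6)
  expect_true(all(first$lat_peak_vm_MPa <= first$lat_peak_pressure_MPa))
  # worn-state stance peak at least the unworn value at matching phase
  last <- res$last_cycle
  stance <- first$t < 0.6
  expect_gte(max(last$lat_peak_vm_MPa[stance]),
             max(first$lat_peak_vm_MPa[stance]))
})

test_that("zero axial force yields an all-zero lateral trajectory", {
  j <- make_mirror_joint()
  cfg <- joint_config()
  sols <- lapply(1:5, function(i)
    solve_joint_equilibrium(j$medial, j$lateral, 0, cfg,
                            pe_foundation(), pe_foundation())$lateral)
  traj <- lateral_stress_trajectory(seq(0, 0.8, by = 0.2), sols, 0.475)
  expect_true(all(traj$peak_pressure_MPa == 0))
  expect_true(all(traj$peak_von_mises_MPa == 0))
})
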