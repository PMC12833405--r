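test_that("foundation modulus follows the bonded-layer formula", {
  expect_equal(foundation_modulus(foundation_params(940, 0.46, 8)),
               940 * (1 - 0.46) / ((1 + 0.46) * (1 - 2 * 0.46) * 8),
               tolerance = 1e-12)
  expect_equal(round(foundation_modulus(foundation_params(940, 0.46, 8)), 2),
               543.24)
  expect_equal(foundation_modulus(foundation_params(1, 0, 1)), 1)
  # strictly increasing as nu -> 0.5 at fixed E, t
  nus <- seq(0, 0.49, by = 0.07)
  ks <- vapply(nus, function(nu)
    foundation_modulus(foundation_params(940, nu, 8)), numeric(1L))
  expect_true(all(diff(ks) > 0))
  expect_error(foundation_params(940, 0.5, 8), "0.5")
})

test_that("zero target load yields an empty contact", {
  sol <- solve_contact(sphere_on_flat(1), kinematic_state(), 0,
                       pe_foundation())
  expect_equal(sol$total_force, 0)
  expect_equal(sol$contact_area, 0)
  expect_equal(sol$peak_pressure, 0)
})

test_that("fully conforming pair carries uniform pressure F / A", {
  comp <- conforming_pair(side = 20)
  fnd <- pe_foundation()
  sol <- solve_contact(comp, kinematic_state(), 1000, fnd)
  expect_equal(sol$contact_area, 400, tolerance = 1e-9)
  p <- sol$pressure[sol$active]
  expect_equal(p, rep(1000 / 400, length(p)), tolerance = 1e-6)
})

test_that("force balance holds within 0.1% across loads and kinematics", {
  comp <- make_medial_compartment(implant_spec(), 1)
  fnd <- pe_foundation()
  for (f in c(168, 500, 1500, 2600))
    for (ap in c(0, 3)) {
      sol <- solve_contact(comp, kinematic_state(ap_translation = ap), f, fnd)
      expect_lt(abs(sol$total_force - f) / f, 0.001)
      expect_true(all(sol$pressure >= 0))
      expect_equal(sol$contact_area,
                   sum(comp$tibial$nodal_area[sol$pressure > 0]))
    }
})

test_that("sphere on a flat layer matches the thin-layer closed form", {
  comp <- sphere_on_flat(resolution = 4)
  fnd <- pe_foundation()
  k <- foundation_modulus(fnd)
  sol <- solve_contact(comp, kinematic_state(), 1000, fnd)
  p0 <- sqrt(k * 1000 / (pi * 28))
  a0 <- (4 * 1000 * 28 / (pi * k))^0.25
  expect_lt(abs(sol$peak_pressure - p0) / p0, 0.20)
  expect_lt(abs(sqrt(sol$contact_area / pi) - a0) / a0, 0.20)
})

test_that("solver pressures equal the direct foundation response node for node", {
  comp <- flat_toy_compartment(n = 10, dx = 1, height = 8)
  # dish the toy surface so the patch is interior
  x <- comp$tibial$x
  comp$tibial$height <- comp$tibial$height +
    0.02 * (outer(x^2, rep(1, 10)) + outer(rep(1, 10), x^2))
  fnd <- pe_foundation()
  k <- foundation_modulus(fnd)
  sol <- solve_contact(comp, kinematic_state(), 500, fnd)
  # independent brute-force evaluation of k * max(0, penetration) at the
  # solved approach, from raw heights and the analytic condyle drop
  rs <- 28; rc <- 22
  drop <- outer(rs - sqrt(rs^2 - x^2), rep(1, 10)) +
    outer(rep(1, 10), rc - sqrt(rc^2 - x^2))
  s <- comp$tibial$height - drop
  h0 <- max(s) - sol$axial_approach
  expect_equal(sol$pressure, k * pmax(0, s - h0), tolerance = 1e-9)
})

test_that("peak pressure changes under 5% when the grid is refined", {
  fnd <- pe_foundation()
  p <- vapply(c(1, 2), function(res) {
    comp <- make_medial_compartment(implant_spec(), res)
    solve_contact(comp, kinematic_state(), 2600, fnd)$peak_pressure
  }, numeric(1L))
  expect_lt(abs(p[2] - p[1]) / p[1], 0.05)
})

test_that("unreachable loads raise a travel-bound error", {
  comp <- sphere_on_flat(1)
  expect_error(solve_contact(comp, kinematic_state(), 1e9, pe_foundation()),
               "travel")
})

test_that("sliding increments compose flexion arc, AP shift and IE rotation", {
  comp <- make_medial_compartment(implant_spec(), 1, center_z = 25)
  still <- sliding_increment(comp, kinematic_state(), kinematic_state())
  expect_true(all(still == 0))
  # pure flexion of 1 deg at sagittal radius 28 mm: arc length everywhere
  s_flex <- sliding_increment(comp, kinematic_state(flexion = 0),
                              kinematic_state(flexion = 1))
  expect_equal(unique(as.vector(s_flex)), 28 * pi / 180, tolerance = 1e-12)
  # pure AP translation of 0.5 mm: 0.5 mm everywhere
  s_ap <- sliding_increment(comp, kinematic_state(ap_translation = 0),
                            kinematic_state(ap_translation = 0.5))
  expect_equal(unique(as.vector(s_ap)), 0.5, tolerance = 1e-12)
  # IE rotation: magnitude grows with the lever arm from the joint axis
  s_ie <- sliding_increment(comp, kinematic_state(),
                            kinematic_state(ie_rotation = 1))
  lever <- sqrt(outer(comp$tibial$x^2, rep(1, length(comp$tibial$z))) +
                  outer(rep(1, length(comp$tibial$x)),
                        (comp$tibial$z + 25)^2))
  expect_equal(s_ie, (pi / 180) * lever, tolerance = 1e-9)
  # masking: inactive nodes report zero sliding
  act <- matrix(FALSE, length(comp$tibial$x), length(comp$tibial$z))
  act[3, 4] <- TRUE
  s_m <- sliding_increment(comp, kinematic_state(),
                           kinematic_state(ap_translation = 1), act)
  expect_equal(sum(s_m > 0), 1L)
})
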