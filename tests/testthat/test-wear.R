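test_that("Archard depth follows the unit contract exactly", {
  p <- archard_params()
  expect_equal(archard_depth_increment(0, 5, p), 0)
  expect_equal(archard_depth_increment(10, 0.01, p), 3.3e-8, tolerance = 1e-15)
  expect_equal(archard_depth_increment(20, 0.005, p), 3.3e-8, tolerance = 1e-15)
  expect_equal(archard_depth_increment(10, 0.02, p),
               2 * archard_depth_increment(10, 0.01, p))
  expect_error(archard_depth_increment(-1, 1, p), ">= 0")
  expect_error(archard_depth_increment(1, -1, p), ">= 0")
})

test_that("cycle accumulation is a commutative sum over increments", {
  set.seed(11)
  n_nodes <- 30; n_t <- 12
  pr <- matrix(runif(n_nodes * n_t, 0, 40), n_nodes, n_t)
  sl <- matrix(runif(n_nodes * n_t, 0, 0.5), n_nodes, n_t)
  d <- accumulate_cycle(pr, sl)
  perm <- sample(n_t)
  expect_equal(accumulate_cycle(pr[, perm], sl[, perm]), d, tolerance = 1e-15)
  # single-increment single-node check: 3.3e-7 * 20 MPa * 0.005 m
  pr1 <- matrix(0, 3, 1); sl1 <- matrix(0, 3, 1)
  pr1[2, 1] <- 20; sl1[2, 1] <- 5   # 5 mm
  expect_equal(accumulate_cycle(pr1, sl1), c(0, 3.3e-8, 0), tolerance = 1e-15)
  expect_true(all(accumulate_cycle(pr * 0, sl) == 0))
  expect_error(accumulate_cycle(pr, sl[, 1:3]), "shape")
})

test_that("uniform recession of a flat patch removes exactly depth x area", {
  comp <- flat_toy_compartment(n = 20, dx = 1, height = 8)
  st <- wear_state(comp)
  prm <- archard_params(cycles_per_step = 1)
  d <- matrix(0.25, 20, 20)
  upd <- apply_wear_step(st, d, comp, prm)
  expect_equal(upd$state$volume_loss, 0.25 * 19 * 19, tolerance = 1e-12)
  expect_equal(upd$state$mass_loss, 0.93 * upd$state$volume_loss,
               tolerance = 1e-12)
  expect_equal(unique(as.vector(comp$tibial$height -
                                  upd$geom$tibial$height)), 0.25)
})

test_that("a 10 mm^3 volume increment weighs 9.3 mg", {
  comp <- flat_toy_compartment(n = 11, dx = 1, height = 8)
  area <- sum(comp$tibial$nodal_area)     # 100 mm^2
  upd <- apply_wear_step(wear_state(comp), matrix(10 / area, 11, 11), comp,
                         archard_params(cycles_per_step = 1))
  expect_equal(upd$state$volume_loss, 10, tolerance = 1e-9)
  expect_equal(upd$state$mass_loss, 9.3, tolerance = 1e-9)
})

test_that("nodal volume bookkeeping matches a triangulated mesh-volume oracle", {
  # curved 20 x 20 bearing patch, compact interior wear field
  n <- 20
  ax <- seq(-9.5, 9.5, by = 1)
  h <- 8 + 0.01 * (outer(ax^2, rep(1, n)) + outer(rep(1, n), ax^2))
  tib <- surface_grid(ax, ax, h)
  comp <- compartment_geometry(make_femoral_surface(implant_spec(), 1), tib,
                               8, "medial_implant", center_z = 0)
  r2 <- outer(ax^2, rep(1, n)) + outer(rep(1, n), ax^2)
  depth <- 0.3 * exp(-r2 / 18)          # essentially zero at the rim
  st <- wear_state(comp)
  upd <- apply_wear_step(st, depth, comp, archard_params(cycles_per_step = 1))

  tri_volume <- function(hm) {          # independent PL mesh integral
    v <- 0
    for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
      v <- v + (hm[i, j] + hm[i + 1, j] + hm[i, j + 1]) / 3 * 0.5 +
        (hm[i + 1, j] + hm[i, j + 1] + hm[i + 1, j + 1]) / 3 * 0.5
    }
    v
  }
  dv_oracle <- tri_volume(comp$tibial$height) -
    tri_volume(upd$geom$tibial$height)
  expect_lt(abs(upd$state$volume_loss - dv_oracle) / dv_oracle, 0.005)
  expect_equal(heightfield_volume(comp$tibial) -
                 heightfield_volume(upd$geom$tibial),
               dv_oracle, tolerance = 1e-9)
})

test_that("recession beyond the remaining thickness halts the simulation", {
  comp <- flat_toy_compartment(n = 10, dx = 1, height = 0.2)
  expect_error(apply_wear_step(wear_state(comp), matrix(0.5, 10, 10), comp,
                               archard_params(cycles_per_step = 1)),
               "thickness")
})

test_that("a zero-step schedule leaves geometry and mass untouched", {
  cfg <- default_config("UKA",
                        overrides = list(n_samples = 50L,
                                         wear = list(n_steps = 0L)))
  res <- run_simulation(cfg)
  expect_equal(res$summary$mass_mg, 0)
  expect_equal(max(res$state$depth), 0)
  expect_identical(res$medial$tibial$height,
                   make_insert_surface(implant_spec(), 1)$height)
})

test_that("mass loss is non-decreasing and equals density times volume", {
  res <- default_ukak_run()
  h <- res$history
  expect_true(all(diff(h$mass_mg) >= 0))
  expect_true(all(diff(h$volume_mm3) >= 0))
  expect_equal(h$mass_mg, 0.93 * h$volume_mm3, tolerance = 1e-9)
  expect_true(all(res$state$depth >= 0))
})

test_that("worn region sits in the central-posterior insert for default gait", {
  res <- default_ukak_run()
  ctr <- wear_centroid(res$state, res$medial)
  expect_lt(ctr[["x"]], 0)                       # posterior half
  expect_lt(abs(ctr[["z"]]), 26 / 4)             # central band in ML
})

test_that("Laplacian smoothing keeps the field inside its original range", {
  set.seed(3)
  f <- matrix(runif(100), 10, 10)
  g <- ukawear:::smooth_field(f, lambda = 0.5, passes = 2L)
  expect_lte(max(g), max(f))
  expect_gte(min(g), min(f))
  expect_equal(dim(g), dim(f))
})
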