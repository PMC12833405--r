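test_that("lattice construction matches the requested footprint and density", {
  spec <- implant_spec()
  fem <- make_femoral_surface(spec, resolution = 1)
  expect_length(fem$x, 46L)   # 45 mm AP at 1 node/mm
  expect_length(fem$z, 21L)   # 20 mm ML
  ins <- make_insert_surface(spec, resolution = 1)
  expect_length(ins$x, 42L)
  expect_length(ins$z, 27L)
})

test_that("nodal areas integrate the footprint exactly", {
  for (res in c(1, 2)) {
    ins <- make_insert_surface(implant_spec(), res)
    expect_equal(sum(ins$nodal_area), 41 * 26, tolerance = 1e-12)
    fem <- make_femoral_surface(implant_spec(), res)
    expect_equal(sum(fem$nodal_area), 45 * 20, tolerance = 1e-12)
  }
})

test_that("surface normals are unit length everywhere", {
  ins <- make_insert_surface(implant_spec(), 1)
  n <- surface_normals(ins)
  len <- sqrt(n$nx^2 + n$ny^2 + n$nz^2)
  expect_true(all(abs(len - 1) < 1e-9))
})

test_that("biconvex femoral surface has its apex at h0 and bounded sagitta", {
  spec <- implant_spec(femoral_sagittal_radius = 1000,
                       femoral_coronal_radius = 1000,
                       insert_sagittal_radius = 1000,
                       insert_coronal_radius = 1000)
  fem <- make_femoral_surface(spec, 1, h0 = 0)
  # near-flat radii: along the sagittal midline the drop is the sagitta at
  # r = 22.5 mm (< 0.26 mm for R = 1000); over the whole footprint the two
  # arc sagittas add, bounding the drop by 0.31 mm
  expect_true(all(abs(fem$height[, fem$z == 0]) <= 0.26))
  expect_true(all(abs(fem$height) <= sagitta(22.5, 1000) +
                    sagitta(10, 1000) + 1e-12))
  # apex value: analytic evaluation at the centre
  expect_equal(femoral_drop(fem, 0, 0)[1, 1], 0)
  # default radii: apex is the height-field maximum (h = h0 - sagitta);
  # the even AP lattice brackets the apex at x = +/- 0.5 mm
  fem2 <- make_femoral_surface(implant_spec(), 1, h0 = 3)
  expect_equal(max(fem2$height), 3 - sagitta(0.5, 28), tolerance = 1e-12)
  expect_equal(femoral_drop(fem2, 0, 0)[1, 1], 0)
})

test_that("footprint half-extent beyond the articular radius is rejected", {
  spec <- implant_spec(femoral_sagittal_radius = 20)  # < 45/2
  expect_error(make_femoral_surface(spec, 1), "exceeds articular radius")
  expect_error(implant_spec(insert_sagittal_radius = 20),
               "conformity")  # insert radius below femoral radius
})

test_that("insert thickness is minimal at the dish bottom and equals spec", {
  ins <- make_insert_surface(implant_spec(), 1)
  expect_equal(min(ins$height), 8, tolerance = 1e-3)
  ins2 <- make_insert_surface(implant_spec(), 2)
  expect_gte(min(ins2$height), 8)
})

test_that("heights are analytic: doubling resolution reproduces shared nodes", {
  spec <- implant_spec()
  for (maker in list(make_femoral_surface, make_insert_surface)) {
    g1 <- maker(spec, 1)
    g2 <- maker(spec, 2)
    expect_equal(g2$x[seq(1, length(g2$x), 2)], g1$x)
    expect_identical(g2$height[seq(1, length(g2$x), 2),
                               seq(1, length(g2$z), 2)],
                     g1$height)
  }
})

test_that("equal-radius insert nests on the femoral surface with zero gap", {
  spec <- implant_spec(insert_sagittal_radius = 28, insert_coronal_radius = 22,
                       femoral_sagittal_radius = 28,
                       femoral_coronal_radius = 22)
  comp <- compartment_geometry(make_femoral_surface(spec, 1),
                               make_insert_surface(spec, 1),
                               8, "medial_implant")
  s <- ukawear:::compartment_support(comp)
  inside <- is.finite(s)
  expect_true(any(inside))
  # support height constant over the covered region <=> uniform zero gap
  expect_lt(diff(range(s[inside])), 1e-9)
})

test_that("lower conformity strictly widens the apex-aligned gap off-apex", {
  tight <- implant_spec(insert_sagittal_radius = 45,
                        insert_coronal_radius = 30)
  loose <- implant_spec(insert_sagittal_radius = 60,
                        insert_coronal_radius = 40)
  x <- seq(-18, 18, by = 1); z <- seq(-9, 9, by = 1)
  gap <- function(spec) {
    outer(sagitta(x, spec$femoral_sagittal_radius) -
            sagitta(x, spec$insert_sagittal_radius),
          sagitta(z, spec$femoral_coronal_radius) -
            sagitta(z, spec$insert_coronal_radius), "+")
  }
  d <- gap(loose) - gap(tight)
  off_apex <- !(outer(x == 0, z == 0, "&"))
  expect_true(all(d[off_apex] > 0))
  expect_equal(d[x == 0, z == 0], 0)
})

test_that("lateral cartilage compartment honours its configuration", {
  lat <- make_lateral_cartilage_surface(lateral_config(), 1)
  expect_s3_class(lat, "compartment_geometry")
  expect_identical(lat$label, "lateral_cartilage")
  # default lateral footprint within +/- 30% of the medial insert footprint
  a_lat <- prod(lat$tibial$footprint)
  expect_lt(abs(a_lat - 41 * 26) / (41 * 26), 0.30)
  # zero meniscus contribution: layer thickness is cartilage thickness
  lat0 <- make_lateral_cartilage_surface(
    lateral_config(meniscus_effective_thickness = 0), 1)
  expect_equal(lat0$layer_thickness,
               lateral_config()$cartilage_thickness)
  expect_equal(lat$layer_thickness,
               lateral_config()$cartilage_thickness +
                 lateral_config()$meniscus_effective_thickness)
})

test_that("mesh and lattice exports are readable and consistent", {
  g <- make_insert_surface(implant_spec(), 1)
  ply <- tempfile(fileext = ".ply")
  vtk <- tempfile(fileext = ".vtk")
  csv <- tempfile(fileext = ".csv")
  write_surface_ply(g, ply)
  write_surface_vtk(g, vtk)
  write_surface_csv(g, csv)
  lines <- readLines(ply)
  nv <- length(g$x) * length(g$z)
  expect_equal(lines[1], "ply")
  expect_true(paste("element vertex", nv) %in% lines)
  expect_true(any(grepl("^POLYGONS", readLines(vtk))))
  df <- read.csv(csv)
  expect_equal(nrow(df), nv)
  expect_equal(sum(df$area), 41 * 26, tolerance = 1e-9)
})
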