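test_that("radius profile follows the Gaussian bulge closed form", {
  geom <- vessel_geometry(0.1, 0.01, bulge_amplitude = 0.005,
                          bulge_center = 0.05, bulge_width = 0.02)
  ## straight tube: no bulge anywhere
  straight <- vessel_geometry(0.1, 0.01)
  expect_equal(radius_profile(straight, c(0, 0.03, 0.1)), rep(0.01, 3))
  ## peak of the Gaussian at the bulge centre, both sides when symmetric
  expect_equal(radius_profile(geom, 0.05, "upper"), 0.015)
  expect_equal(radius_profile(geom, 0.05, "lower"), 0.015)
  ## one bulge-width offset: frozen value 10 + 5 exp(-1/2) mm
  expect_equal(radius_profile(geom, 0.07), 0.01 + 0.005 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(1e3 * radius_profile(geom, 0.07), 13.0327, tolerance = 1e-4)
  expect_error(radius_profile(geom, 0.11), "outside")
  expect_error(radius_profile(geom, -0.01), "outside")
})

test_that("asymmetry splits the bulge between sides, averaging to the mean", {
  geom <- vessel_geometry(0.1, 0.01, bulge_amplitude = 0.004, asymmetry = 0.5)
  zc <- geom$bulge_center
  up <- radius_profile(geom, zc, "upper")
  lo <- radius_profile(geom, zc, "lower")
  expect_equal(up, 0.01 + 0.004 * 1.5)
  expect_equal(lo, 0.01 + 0.004 * 0.5)
  expect_equal((up + lo) / 2, radius_profile(geom, zc, "mean"))
  ## asymmetry = 1: bulge entirely on one side
  g1 <- vessel_geometry(0.1, 0.01, bulge_amplitude = 0.004, asymmetry = 1)
  expect_equal(radius_profile(g1, zc, "lower"), 0.01)
})

test_that("geometry constructor rejects degenerate inputs", {
  expect_error(vessel_geometry(-0.1, 0.01), "positive")
  expect_error(vessel_geometry(0.1, 0), "positive")
  expect_error(vessel_geometry(0.1, 0.01, bulge_amplitude = -1e-3), ">= 0")
  expect_error(vessel_geometry(0.1, 0.01, wall_thickness = 0), "positive")
  expect_error(vessel_geometry(0.1, 0.01, asymmetry = 1.2), "\\[0, 1\\]")
})

test_that("mesh measures match the analytic lumen measure within 0.5%", {
  for (mode in c("axisymmetric-2D", "planar-2D")) {
    straight <- vessel_geometry(0.08, 0.01)
    m <- build_mesh(straight, list(nz = 21, nr = 11, nw = 5), mode = mode)
    expect_lt(abs(lumen_measure(m) / analytic_lumen_measure(straight, mode) - 1),
              5e-3)
  }
  bulged <- vessel_geometry(0.08, 0.01, bulge_amplitude = 0.006,
                            bulge_width = 0.012)
  m <- build_mesh(bulged, list(nz = 41, nr = 21, nw = 5))
  err1 <- abs(lumen_measure(m) / analytic_lumen_measure(bulged) - 1)
  expect_lt(err1, 5e-3)
  ## refinement strictly reduces the discretization error
  m2 <- refine(m, 2)
  err2 <- abs(lumen_measure(m2) / analytic_lumen_measure(bulged) - 1)
  expect_lt(err2, err1)
})

test_that("mesh construction guarantees: wall span, positivity, labels", {
  geom <- vessel_geometry(0.06, 0.008, bulge_amplitude = 0.004,
                          asymmetry = 0.4)
  mesh <- build_mesh(geom, mode = "planar-2D")
  ## outer-wall nodes sit exactly wall_thickness from their interface nodes
  for (sd in names(mesh$walls)) {
    w <- mesh$walls[[sd]]
    d <- sqrt((w$Z[, mesh$nw] - w$Z[, 1])^2 + (w$Y[, mesh$nw] - w$Y[, 1])^2)
    expect_equal(d, rep(geom$wall_thickness, mesh$nz), tolerance = 1e-12)
  }
  ## strictly positive cell measures everywhere, >= 3 wall layers
  expect_true(all(lumen_cell_volumes(mesh) > 0))
  expect_gte(mesh$nw - 1L, 3L)
  for (sd in names(mesh$walls))
    expect_true(all(abs(wall_cell_volumes(mesh, sd)) > 0))
  ## two wall sides in planar mode, one in axisymmetric
  expect_setequal(names(mesh$walls), c("upper", "lower"))
  ma <- build_mesh(vessel_geometry(0.06, 0.008))
  expect_identical(names(ma$walls), "outer")
})

test_that("axisymmetric mode rejects asymmetric bulges", {
  geom <- vessel_geometry(0.06, 0.008, bulge_amplitude = 0.004,
                          asymmetry = 0.3)
  expect_error(build_mesh(geom, mode = "axisymmetric-2D"), "asymmetric")
})

test_that("refine scales per-direction node counts by ceiling(factor * n)", {
  mesh <- build_mesh(vessel_geometry(0.06, 0.008),
                     list(nz = 20, nr = 10, nw = 5))
  m1 <- refine(mesh, 1.1)
  expect_identical(c(m1$nz, m1$nr, m1$nw),
                   as.integer(ceiling(1.1 * c(20, 10, 5))))
  expect_error(refine(mesh, 1), "> 1")
  ## refining twice by 1.1 ~ once by 1.21, within rounding
  m2 <- refine(m1, 1.1)
  m21 <- refine(mesh, 1.21)
  expect_true(all(abs(c(m2$nz - m21$nz, m2$nr - m21$nr, m2$nw - m21$nw)) <= 1))
})
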