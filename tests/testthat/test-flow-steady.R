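test_that("steady tube WSS matches the Hagen-Poiseuille oracle within 2%", {
  sol <- fx_steady_tube()
  tau <- extract_wss(sol)$sides$top$tau[, 1]
  oracle <- 4 * 0.0035 * 0.2 / 0.01      # 4 mu U / R = 0.28 Pa
  ## fully developed region near the outlet end
  iz <- seq(ceiling(0.75 * length(tau)), length(tau))
  expect_lt(max(abs(tau[iz] / oracle - 1)), 0.02)
})

test_that("steady planar channel WSS matches 3 mu U / H on both walls", {
  mesh <- build_mesh(tube_geom(), mode = "planar-2D")
  sol <- solve_steady(mesh, fluid_properties(), 0.2)
  w <- extract_wss(sol)
  oracle <- 3 * 0.0035 * 0.2 / 0.01
  iz <- seq(40, mesh$nz)
  expect_lt(max(abs(w$sides$top$tau[iz, 1] / oracle - 1)), 0.02)
  expect_lt(max(abs(w$sides$bottom$tau[iz, 1] / oracle - 1)), 0.02)
})

test_that("steady shear is linear in viscosity and antisymmetric in inflow", {
  mesh <- build_mesh(tube_geom(), list(nz = 33, nr = 21, nw = 5))
  base <- solve_steady(mesh, fluid_properties(), 0.2)
  tau1 <- extract_wss(base)$sides$top$tau[, 1]
  ## doubling mu doubles WSS (exactly in the developed limit; the short
  ## Re-dependent inlet adjustment keeps the ratio within ~2% elsewhere)
  thick <- solve_steady(mesh, fluid_properties(viscosity = 0.007), 0.2)
  expect_equal(extract_wss(thick)$sides$top$tau[, 1] / tau1,
               rep(2, length(tau1)), tolerance = 0.02)
  ## reversing the inflow flips the WSS sign everywhere
  rev <- solve_steady(mesh, fluid_properties(), -0.2)
  tau_rev <- extract_wss(rev)$sides$top$tau[, 1]
  expect_true(all(tau_rev < 0))
  expect_equal(tau_rev, -tau1, tolerance = 0.05)
})

test_that("no-slip holds at the interface", {
  vel <- flow_velocity(fx_steady_tube())
  expect_lt(max(abs(vel$uz[, ncol(vel$uz)])) / max(abs(vel$uz)), 0.02)
})

test_that("mass conservation is exact at every cross-section", {
  Q <- mass_flux(fx_steady_tube())
  expect_equal(Q, rep(pi * 0.01^2 * 0.2, length(Q)), tolerance = 1e-12)
})

test_that("creeping flow over a symmetric bulge gives fore-aft symmetric WSS", {
  geom <- vessel_geometry(0.08, 0.01, bulge_amplitude = 0.004,
                          bulge_center = 0.04, bulge_width = 0.012)
  mesh <- build_mesh(geom, list(nz = 41, nr = 21, nw = 5))
  sol <- solve_steady(mesh, fluid_properties(), 1e-4)   # Re << 1
  tau <- extract_wss(sol)$sides$top$tau[, 1]
  ## compare against the axially mirrored profile (skip the ends where
  ## inlet/outlet conditions differ)
  idx <- 6:36
  mirrored <- rev(tau)[idx]
  expect_lt(max(abs(tau[idx] - mirrored)) / max(abs(tau)), 0.03)
})

test_that("WSS error against the analytic oracle decreases under refinement", {
  geom <- tube_geom()
  errs <- sapply(list(c(29, 17), c(41, 25), c(57, 33)), function(rs) {
    mesh <- build_mesh(geom, list(nz = rs[1], nr = rs[2], nw = 5))
    tau <- extract_wss(solve_steady(mesh, fluid_properties(), 0.2))$sides$top$tau[, 1]
    abs(tau[rs[1]] / 0.28 - 1)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("a too-small iteration budget raises a solver error with residuals", {
  mesh <- build_mesh(tube_geom(), list(nz = 21, nr = 11, nw = 5))
  err <- tryCatch(solve_steady(mesh, fluid_properties(), 0.2, max_iter = 1L),
                  error = identity)
  expect_s3_class(err, "aneuNO_solver_error")
  expect_true(is.numeric(err$residuals) && length(err$residuals) >= 1)
})

test_that("recovered steady pressure gradient matches Poiseuille", {
  sol <- fx_steady_tube()
  p <- flow_pressure(sol)
  mesh <- sol$mesh
  ## centerline pressure slope over the developed mid region
  iz <- 15:45
  slope <- stats::coef(stats::lm(p[iz, 1] ~ mesh$z[iz]))[2]
  oracle <- -8 * 0.0035 * 0.2 / 0.01^2
  expect_lt(abs(slope / oracle - 1), 0.10)
})
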