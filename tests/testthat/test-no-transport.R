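test_that("hyperbolic production law reproduces its closed-form values", {
  expect_identical(production_rate(0), 2.13)
  expect_equal(production_rate(3.5), 2.13 + 457.5 / 2)   # half-saturation
  expect_equal(production_rate(1e12), 2.13 + 457.5, tolerance = 1e-9)
  ## monotone nondecreasing in |tau|, sign-independent
  tau <- seq(0, 20, by = 0.5)
  expect_true(all(diff(production_rate(tau)) > 0))
  expect_equal(production_rate(-4), production_rate(4))
  expect_error(production_rate(NaN), "finite")
})

test_that("lumen reaction combines quadratic oxidation and linear scavenging", {
  expect_identical(lumen_reaction(0), 0)
  expect_equal(lumen_reaction(1), 7.56e-6 + 2.3)
  expect_error(lumen_reaction(-1), "negative")
})

test_that("well-mixed decay follows the closed-form exponential", {
  skip_if_not_installed("deSolve")
  ## independent integration of the reaction law with koxgen negligible
  p <- transport_params()
  sol <- deSolve::ode(c(c = 1), seq(0, 1, by = 0.01),
                      function(t, y, parms) list(-lumen_reaction(y, p)),
                      parms = NULL)
  ratio <- sol[nrow(sol), "c"]
  expect_equal(unname(ratio), exp(-2.3), tolerance = 1e-4)
  expect_equal(exp(-2.3), 0.1003, tolerance = 1e-3)
})

test_that("zero endothelial production gives an identically zero field", {
  p <- transport_params(Rbasal = 1e-30, Rmax = 1e-30)
  no <- solve_no(fx_tube_mesh(), fx_steady_tube(), p)
  expect_lt(max(abs(no$cl)), 1e-15)
  expect_lt(max(abs(unlist(no$cw))), 1e-15)
})

test_that("wall transport matches the 1D slab reaction-diffusion oracle", {
  no <- solve_no(fx_tube_mesh(), fx_steady_tube(),
                 fixed_interface = list(outer = 100))
  fvg <- no$fvg
  i <- ceiling(fvg$nci / 2)
  kidx <- (seq_len(fvg$nw - 1L) - 1L) * fvg$nci + i
  x <- sqrt((fvg$walls$outer$center$z[i, ] - fvg$walls$outer$iface$mz[i])^2 +
            (fvg$walls$outer$center$y[i, ] - fvg$walls$outer$iface$my[i])^2)
  cw <- no$cw$outer[kidx, 1]
  L <- sqrt(8.48e-10 / 0.01)
  expect_equal(L, 0.291e-3, tolerance = 1e-3)
  ## concentration one decay length into the wall: c0 * e^-1 within 1%
  c_at_L <- stats::approx(x, cw, xout = L)$y
  expect_lt(abs(c_at_L / (100 * exp(-1)) - 1), 0.01)
  ## near-interface wall cells track the decaying closed form within 2%
  Tk <- 2e-3
  exact <- 100 * cosh((Tk - x) / L) / cosh(Tk / L)
  expect_lt(max(abs(cw[1:5] / exact[1:5] - 1)), 0.02)
})

test_that("concentrations are non-negative without clipping", {
  no <- fx_no_steady()
  expect_gte(min(no$cl), -1e-6)
  expect_gte(min(unlist(no$cw)), -1e-6)
  expect_gte(min(no$cl), 0)           # M-matrix scheme: exactly clip-free
})

test_that("interface rows enforce flux continuity with the production source", {
  no <- fx_no_steady()
  fvg <- no$fvg; p <- no$params
  ifc <- fvg$walls$outer$iface
  cs <- no$cs$outer[, 1]
  cP <- no$cl[ifc$lumP, 1]
  cW <- no$cw$outer[seq_len(fvg$nci), 1]
  q <- no$q_s_trace[[1]]$outer
  resid <- p$Dl * ifc$area / ifc$dL * (cs - cP) +
    p$Dw * ifc$area / ifc$dW * (cs - cW) - q * ifc$area
  expect_lt(max(abs(resid)) / max(q * ifc$area), 1e-10)
})

test_that("source-sink balance closes at steady state", {
  bal <- no_balance(fx_no_steady())
  expect_lt(bal$relative_imbalance, 0.01)
  expect_lt(bal$relative_imbalance, 1e-8)   # telescoping scheme: exact
  expect_gt(bal$production, 0)
})

test_that("steady tube interface NO sits at the physiological nM level", {
  no <- fx_no_steady()
  cs <- no$cs$outer[, 1]
  expect_gt(mean(cs), 1)
  expect_lt(mean(cs), 1000)
})

test_that("stronger scavenging depresses, stronger production raises, surface NO", {
  base <- fx_no_steady()
  hot <- solve_no(fx_tube_mesh(), fx_steady_tube(),
                  transport_params(kery = 23))
  expect_true(all(hot$cs$outer[, 1] < base$cs$outer[, 1]))
  rich <- solve_no(fx_tube_mesh(), fx_steady_tube(),
                   transport_params(Rmax = 2 * 457.5))
  expect_true(all(rich$cs$outer[, 1] >= base$cs$outer[, 1]))
})

test_that("solver contracts: mesh mismatch is rejected", {
  other <- build_mesh(tube_geom(), list(nz = 21, nr = 11, nw = 5))
  expect_error(solve_no(other, fx_steady_tube()), "different mesh")
})

test_that("grid-independence protocol converges on the default tube", {
  rep <- mesh_independence_study(tube_geom(),
                                 resolution = list(nz = 17, nr = 9, nw = 5),
                                 max_refinements = 6L)
  expect_true(rep$converged)
  deltas <- rep$trace$delta[!is.na(rep$trace$delta)]
  expect_lt(deltas[length(deltas)], 0.05)
  expect_false(is.null(rep$accepted))
})

test_that("an unattainable threshold exhausts the budget with a failure flag", {
  rep <- mesh_independence_study(tube_geom(),
                                 resolution = list(nz = 13, nr = 7, nw = 4),
                                 threshold = 0, max_refinements = 2L)
  expect_false(rep$converged)
  expect_null(rep$accepted)
  expect_identical(nrow(rep$trace), 3L)
})

test_that("an already-fine mesh is accepted after a single comparison", {
  rep <- mesh_independence_study(tube_geom(),
                                 resolution = list(nz = 41, nr = 25, nw = 9),
                                 max_refinements = 3L)
  expect_true(rep$converged)
  expect_identical(nrow(rep$trace), 2L)
})
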