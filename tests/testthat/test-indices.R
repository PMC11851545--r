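test_that("TAWSS closed forms: constant, rectified sinusoid, sign invariance", {
  t <- seq(0, 1, length.out = 401)
  expect_equal(tawss(rep(2, 401), t), 2)
  expect_equal(tawss(sin(2 * pi * t), t), 2 / pi, tolerance = 1e-4)
  tau <- 0.7 + 0.5 * sin(2 * pi * t)
  expect_equal(tawss(tau, t), tawss(-tau, t))
  expect_error(tawss(numeric(0), numeric(0)), "quadrature|column")
})

test_that("OSI closed forms and bounds", {
  t <- seq(0, 1, length.out = 401)
  expect_equal(osi(rep(1.5, 401), t), 0)                 # unidirectional
  expect_equal(osi(sin(2 * pi * t), t), 0.5, tolerance = 1e-6)
  ## tau = 1 + sin stays non-negative: |mean| = mean|.| => OSI = 0
  expect_equal(osi(1 + sin(2 * pi * t), t), 0, tolerance = 1e-9)
  expect_warning(o <- osi(rep(0, 401), t), "undefined")
  expect_true(is.na(o))
})

test_that("RRT and ECAP formula arithmetic and limits", {
  expect_equal(rrt(2, 0), 0.5)
  expect_equal(ecap(2, 0), 0)
  expect_equal(rrt(0.5, 0.25), 4)
  expect_equal(ecap(0.5, 0.25), 0.5)
  o <- c(0.3, 0.4, 0.45, 0.49, 0.499)
  expect_true(all(diff(rrt(1, o)) > 0))                  # RRT -> Inf monotonically
  expect_identical(rrt(1, 0.5), Inf)
  expect_error(rrt(0, 0.2), "TAWSS > 0")
})

test_that("TAWSSG reduces to the tangential derivative magnitude", {
  t <- c(0, 1)
  s <- seq(0, 2 * pi, length.out = 101)
  expect_equal(tawssg(cbind(rep(3, 101), rep(3, 101)), s, t),
               rep(0, 101), tolerance = 1e-12)
  lin <- 2.5 * s
  expect_equal(tawssg(cbind(lin, lin), s, t), rep(2.5, 101),
               tolerance = 1e-9)
  sn <- sin(s)
  g <- tawssg(cbind(sn, sn), s, t)
  expect_lt(max(abs(g[5:97] - abs(cos(s[5:97])))), 2e-3)
  expect_error(tawssg(matrix(1, 1, 2), 1, t), "two interface")
})

test_that("TAcNO averages time first, then space", {
  t <- seq(0, 1, length.out = 201)
  expect_equal(tacno(matrix(50, 3, 201), t), 50)
  osc <- matrix(rep(50 + 10 * sin(2 * pi * t), 2), 2, byrow = TRUE)
  expect_equal(tacno(osc, t), 50, tolerance = 1e-6)
  expect_equal(tacno(c(10, 30)), 20)
  expect_equal(tacno(c(10, 30), weights = c(3, 1)), 15)
  expect_error(tacno(matrix(0, 0, 3), t = 1:3), "empty")
})

test_that("steady flow index field: OSI = 0, RRT = 1/TAWSS, identities exact", {
  idx <- compute_indices(fx_steady_tube(), fx_no_steady())
  expect_true(all(idx$OSI == 0))
  expect_equal(idx$RRT, 1 / idx$TAWSS, tolerance = 1e-12)
  expect_true(all(idx$ECAP == 0))
  expect_true(all(idx$TAWSS >= 0))
  expect_true(all(idx$TAcNO > 0))
})

test_that("pulsatile index field satisfies the algebraic invariants", {
  idx <- compute_indices(fx_pulsatile_tube())
  expect_true(all(idx$OSI >= 0 & idx$OSI <= 0.5))
  ## reversing sinusoid on a small mean: appreciable oscillation
  expect_gt(max(idx$OSI), 0.1)
  ok <- idx$OSI < 0.5
  expect_equal(idx$RRT[ok] * (1 - 2 * idx$OSI[ok]) * idx$TAWSS[ok],
               rep(1, sum(ok)), tolerance = 1e-12)
  expect_equal(idx$ECAP * idx$TAWSS, idx$OSI, tolerance = 1e-12)
})

test_that("index quadrature is converged in time on the Womersley fixture", {
  ## closed-form wall shear series at two time resolutions
  wf <- fx_wave_sin()
  nu <- fluid_properties()$nu
  tau_series <- function(nt) {
    t <- seq(0, 1, length.out = nt + 1)
    st <- developed_pulsatile_state(1, t, wf, nu, "tube", R = 0.01)
    list(t = t, tau = 0.0035 * st$omega)
  }
  a <- tau_series(100); b <- tau_series(200)
  expect_lt(abs(tawss(a$tau, a$t) / tawss(b$tau, b$t) - 1), 0.005)
  expect_lt(abs(osi(a$tau, a$t) - osi(b$tau, b$t)), 0.005)
})
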