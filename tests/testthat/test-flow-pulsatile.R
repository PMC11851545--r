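test_that("constant-inflow pulsatile solve reproduces the steady solution", {
  mesh <- build_mesh(tube_geom(), list(nz = 33, nr = 21, nw = 5))
  wf <- waveform_from_coefficients(1, 0.2)
  puls <- solve_pulsatile(mesh, fluid_properties(), wf,
                          cycles = 2L, steps_per_cycle = 40L)
  stead <- solve_steady(mesh, fluid_properties(), 0.2)
  tau_p <- extract_wss(puls)$sides$top$tau
  tau_s <- extract_wss(stead)$sides$top$tau[, 1]
  expect_lt(max(abs(tau_p[, ncol(tau_p)] - tau_s)) / max(abs(tau_s)), 0.01)
})

test_that("pulsatile tube flow matches the Womersley closed form within 5%", {
  sol <- fx_pulsatile_tube()
  mesh <- sol$mesh
  nu <- sol$props$nu
  iz <- which.min(abs(mesh$z - 0.7 * 0.08))
  uc <- sapply(seq_along(sol$times), function(k) flow_velocity(sol, k)$uz[iz, 1])
  tt <- sol$times - sol$times[1]
  ex <- womersley_velocity(0, tt, sol$waveform, 0.01, nu)[1, ]
  expect_lt(max(abs(uc - ex)) / max(abs(ex)), 0.05)
  ## first-harmonic amplitude and phase
  X <- cbind(1, cos(2 * pi * tt), sin(2 * pi * tt))
  cs <- qr.solve(X, uc); ce <- qr.solve(X, ex)
  expect_lt(abs(sqrt(sum(cs[2:3]^2)) / sqrt(sum(ce[2:3]^2)) - 1), 0.05)
  expect_lt(abs(atan2(cs[3], cs[2]) - atan2(ce[3], ce[2])), 0.05)
})

test_that("periodicity is reached: final two cycles agree in mean WSS", {
  sol <- fx_pulsatile_tube()
  spc <- sol$steps_per_cycle
  tau <- sol$wss$top
  nall <- ncol(tau)
  mean_last <- mean(abs(tau[, (nall - spc):nall]))
  mean_prev <- mean(abs(tau[, (nall - 2 * spc):(nall - spc)]))
  expect_lt(abs(mean_last / mean_prev - 1), 0.01)
})

test_that("the CFL guard names the offending step size", {
  mesh <- build_mesh(tube_geom(), list(nz = 33, nr = 15, nw = 5))
  wf <- waveform_from_coefficients(1, 1.0, a = 0, b = 2.0)
  err <- tryCatch(
    solve_pulsatile(mesh, fluid_properties(), wf, cycles = 1L,
                    steps_per_cycle = 4L),
    error = identity)
  expect_s3_class(err, "aneuNO_solver_error")
  expect_match(conditionMessage(err), "dt = ")
  expect_match(conditionMessage(err), "steps_per_cycle")
})

test_that("extract_wss returns signed final-cycle series per wall side", {
  sol <- fx_pulsatile_tube()
  w <- extract_wss(sol)
  expect_identical(ncol(w$sides$top$tau), sol$steps_per_cycle + 1L)
  expect_identical(nrow(w$sides$top$tau), sol$mesh$nz)
  ## zero-mean driving harmonic with small positive mean flow => shear
  ## reverses during the cycle (signed series)
  expect_true(any(w$sides$top$tau < 0) && any(w$sides$top$tau > 0))
  full <- extract_wss(sol, final_cycle_only = FALSE)
  expect_identical(ncol(full$sides$top$tau), length(sol$times_all))
})
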