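test_that("Fourier fit recovers constant and single-harmonic signals", {
  t <- seq(0, 1, length.out = 40)
  wf <- fit_waveform(data.frame(time_s = t, velocity_m_per_s = rep(0.3, 40)),
                     K = 3, period = 1)
  expect_equal(wf$a0, 0.3, tolerance = 1e-12)
  expect_true(all(abs(c(wf$a, wf$b)) < 1e-10))

  v <- sin(2 * pi * t)
  wf1 <- fit_waveform(cbind(t, v), K = 1, period = 1)
  expect_equal(wf1$b[1], 1, tolerance = 1e-8)
  expect_lt(abs(wf1$a0), 1e-10)
  expect_lt(abs(wf1$a[1]), 1e-8)
  ## reconstruction is T-periodic
  expect_equal(eval_waveform(wf1, 0.3), eval_waveform(wf1, 1.3),
               tolerance = 1e-12)
})

test_that("triphasic fixture waveform fits to < 1% of peak with K = 8", {
  s <- make_waveform("triphasic-aortic", period = 1, peak_velocity = 0.5)
  wf <- fit_waveform(s, K = 8, period = 1)
  expect_lt(wf$residual_rms, 0.01 * max(abs(s$velocity_m_per_s)))
  ## the fitted mean is forward
  expect_gt(wf$a0, 0)
})

test_that("fit contracts: sample count, monotone times, period", {
  t <- seq(0, 1, length.out = 10)
  expect_error(fit_waveform(cbind(t, t), K = 5), "2K\\+1")
  expect_error(fit_waveform(cbind(rev(t), t), K = 2), "increasing")
  expect_error(fit_waveform(cbind(t, t), K = 2, period = -1), "positive")
})

test_that("waveform CSV round-trips and rejects malformed headers", {
  s <- make_waveform("sinusoidal", peak_velocity = 0.4)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(s, path, row.names = FALSE)
  back <- read_waveform_csv(path)
  expect_equal(back$velocity_m_per_s, s$velocity_m_per_s)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = 1:3, v = 1:3), bad, row.names = FALSE)
  expect_error(read_waveform_csv(bad), "time_s")
  expect_error(read_waveform_csv(tempfile()), "not found")
})
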