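test_that("waveform presets have their defining shapes", {
  cst <- make_waveform("constant", peak_velocity = 0.2)
  expect_true(all(cst$velocity_m_per_s == 0.2))
  sn <- make_waveform("sinusoidal", peak_velocity = 0.3)
  expect_lt(abs(mean(sn$velocity_m_per_s[-1])), 1e-10)   # zero-mean
  wf <- fit_waveform(sn, K = 3, period = 1)
  expect_gt(abs(wf$b[1]), 10 * max(abs(c(wf$a, wf$b[-1]))))  # K=1 dominates
  ## triphasic: exactly one contiguous reversal interval per period
  tri <- make_waveform("triphasic-aortic", peak_velocity = 0.5)
  v <- tri$velocity_m_per_s
  neg <- rle(v < -1e-12)
  expect_identical(sum(neg$values), 1L)
  expect_gt(mean(v), 0)
  expect_error(make_waveform("square"), "arg")
})

test_that("noiseless coupling is recovered exactly by the analysis chain", {
  idx <- fx_fake_index_field()
  geom <- fx_study_geom()
  g <- make_ilt_from_no(idx, geom, beta = -40, sigma = 0, model = "one-sided",
                        seed = 3)
  tab <- build_section_table(geom, g$ilt, idx)
  fit <- suppressWarnings(correlate_area_no(tab))
  expect_equal(fit$slope, -40, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  ## drawn areas equal the truth where positive (area inversion is exact)
  expect_equal(tab$area_mm2, g$truth$area_drawn_mm2, tolerance = 1e-9)
})

test_that("one-sided model places thrombus on the lower-NO side", {
  z <- seq(0, 60, by = 5)
  idx <- rbind(data.frame(side = "top", z_mm = z, TAcNO = 5 + 0.01 * z),
               data.frame(side = "bottom", z_mm = z, TAcNO = 8 + 0.01 * z))
  g <- make_ilt_from_no(idx, fx_study_geom(), beta = -40, sigma = 0,
                        alpha = 400, model = "one-sided", seed = 1)
  on <- g$truth$area_drawn_mm2 > 0
  expect_true(any(on))
  expect_true(all(g$ilt$thickness[on, "upper"] > 0))   # "top" is the NO-poor side
  expect_true(all(g$ilt$thickness[, "lower"] == 0))
})

test_that("a non-negative coupling slope triggers the regime warning", {
  expect_warning(make_ilt_from_no(fx_fake_index_field(), fx_study_geom(),
                                  beta = 5, sigma = 1, seed = 1),
                 "beta >= 0")
})

test_that("ILT generation is seed-deterministic", {
  idx <- fx_fake_index_field(); geom <- fx_study_geom()
  a <- make_ilt_from_no(idx, geom, beta = -40, target_r2 = 0.8, seed = 11)
  b <- make_ilt_from_no(idx, geom, beta = -40, target_r2 = 0.8, seed = 11)
  d <- make_ilt_from_no(idx, geom, beta = -40, target_r2 = 0.8, seed = 12)
  expect_identical(a$ilt$thickness, b$ilt$thickness)
  expect_false(identical(a$ilt$thickness, d$ilt$thickness))
})

test_that("replicated draws recover the coupling slope and expected R^2", {
  idx <- fx_fake_index_field(); geom <- fx_study_geom()
  beta <- -40
  g0 <- make_ilt_from_no(idx, geom, beta = beta, target_r2 = 0.8, seed = 1)
  slopes <- r2s <- numeric(100)
  for (k in 1:100) {
    g <- make_ilt_from_no(idx, geom, beta = beta, sigma = g0$sigma,
                          alpha = g0$alpha, seed = k)
    fit <- correlate_area_no(build_section_table(geom, g$ilt, idx))
    slopes[k] <- fit$slope; r2s[k] <- fit$r_squared
  }
  expect_lt(abs(mean(slopes) / beta - 1), 0.10)
  sel <- g0$truth$area_true_mm2 > 0
  expected_r2 <- stats::var(beta * g0$truth$TAcNO[sel]) /
    (stats::var(beta * g0$truth$TAcNO[sel]) + g0$sigma^2)
  expect_lt(abs(mean(r2s) - expected_r2), 0.1)
})

test_that("an unbiased coupling (beta = 0) is not mistaken for signal", {
  idx <- fx_fake_index_field(); geom <- fx_study_geom()
  slopes <- numeric(120)
  for (k in seq_along(slopes)) {
    g <- suppressWarnings(make_ilt_from_no(idx, geom, beta = 0, sigma = 20,
                                           alpha = 80, seed = k))
    tab <- build_section_table(geom, g$ilt, idx)
    fit <- tryCatch(correlate_area_no(tab), error = function(e) NULL)
    slopes[k] <- if (is.null(fit)) NA else fit$slope
  }
  expect_lt(abs(mean(slopes, na.rm = TRUE)), 4)   # centred on zero
})

test_that("study bundles are byte-identical under a fixed seed", {
  cfg <- coarse_config(21L)
  d1 <- file.path(tempdir(), "det-a"); d2 <- file.path(tempdir(), "det-b")
  unlink(c(d1, d2), recursive = TRUE)
  make_study(cfg, d1)
  make_study(cfg, d2)
  for (f in c("waveform.csv", "ilt.csv", "ilt_truth.csv", "config.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
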