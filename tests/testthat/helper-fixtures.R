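## Shared fixtures, memoised so expensive solves run once per session.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tube_geom <- function() vessel_geometry(0.08, 0.01)

## default-resolution straight tube, axisymmetric
fx_tube_mesh <- function() memo_fixture("tube_mesh", build_mesh(tube_geom()))

fx_steady_tube <- function() memo_fixture("steady_tube",
  solve_steady(fx_tube_mesh(), fluid_properties(), inflow = 0.2))

fx_no_steady <- function() memo_fixture("no_steady",
  solve_no(fx_tube_mesh(), fx_steady_tube()))

## sinusoidal pulsatile tube (moderate cost: 3 cycles x 100 steps)
fx_wave_sin <- function() waveform_from_coefficients(1, 0.1, a = 0, b = 0.15)

fx_pulsatile_tube <- function() memo_fixture("pulsatile_tube",
  solve_pulsatile(fx_tube_mesh(), fluid_properties(), fx_wave_sin(),
                  cycles = 3L, steps_per_cycle = 100L))

## coarse synthetic study directory (fast: small mesh, 2 cycles x 40 steps)
coarse_config <- function(seed = 7L) {
  cfg <- default_config(seed)
  cfg$solver$nz <- 33L; cfg$solver$nr <- 21L; cfg$solver$nw <- 7L
  cfg$solver$cycles <- 2L; cfg$solver$steps_per_cycle <- 40L
  cfg
}

fx_study_dir <- function() memo_fixture("study_dir", {
  dir <- file.path(tempdir(), "aneuNO-study-fixture")
  unlink(dir, recursive = TRUE)
  stage_generate(dir, coarse_config())
  dir
})

## analytic index field over a 60 mm segment (no solver), for generator
## statistics tests
fx_fake_index_field <- function() {
  z <- seq(0, 60, by = 5)
  tac <- 9 - 3 * exp(-(z - 30)^2 / (2 * 15^2))
  rbind(data.frame(side = "top", z_mm = z, TAcNO = tac),
        data.frame(side = "bottom", z_mm = z, TAcNO = tac))
}

fx_study_geom <- function()
  vessel_geometry(0.06, 0.01, bulge_amplitude = 0.007,
                  bulge_width = 0.010, asymmetry = 0.6)
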