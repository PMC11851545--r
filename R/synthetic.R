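## Synthetic study generator: idealized geometries, inlet waveforms and
## ILT maps with a controlled statistical tie to the computed NO field,
## standing in for patient CTA geometries and ultrasound waveforms.

#' Generate an inlet velocity waveform fixture
#'
#' Presets:
#' \describe{
#'   \item{`triphasic-aortic`}{forward systolic lobe, early-diastolic
#'     reversal, weak late-diastolic forward flow — the qualitative shape
#'     of an infrarenal aortic velocity waveform. Exactly one reversal
#'     interval per period.}
#'   \item{`sinusoidal`}{zero-mean single harmonic.}
#'   \item{`constant`}{steady velocity.}
#' }
#'
#' @param preset one of `"triphasic-aortic"`, `"sinusoidal"`, `"constant"`
#' @param period period T (s)
#' @param peak_velocity systolic peak (m/s); the triphasic preset's mean
#'   is about 0.2 of the peak
#' @param n number of samples over one period
#' @return data.frame with columns `time_s`, `velocity_m_per_s`
#' @export
make_waveform <- function(preset = c("triphasic-aortic", "sinusoidal", "constant"),
                          period = 1.0, peak_velocity = 0.5, n = 64L) {
  preset <- match.arg(preset)
  t <- seq(0, period, length.out = n)
  x <- t / period
  v <- switch(preset,
    "constant" = rep(peak_velocity, n),
    "sinusoidal" = peak_velocity * sin(2 * pi * x),
    "triphasic-aortic" = {
      ## C1 template (squared-sine lobes), band-limited to 8 harmonics so
      ## downstream Fourier fits reconstruct it essentially exactly
      tf <- seq(0, period, length.out = 513L)
      xf <- tf / period
      vv <- numeric(513L)
      sys <- xf < 0.35
      vv[sys] <- peak_velocity * sin(pi * xf[sys] / 0.35)^2
      rev <- xf >= 0.35 & xf < 0.60
      vv[rev] <- -0.25 * peak_velocity * sin(pi * (xf[rev] - 0.35) / 0.25)^2
      late <- xf >= 0.60
      vv[late] <- 0.08 * peak_velocity * sin(pi * (xf[late] - 0.60) / 0.40)^2
      ## small positive perfusion baseline keeps the band-limited signal
      ## from ringing through zero anywhere except the true reversal
      vv <- vv + 0.01 * peak_velocity
      tmpl <- fit_waveform(data.frame(time_s = tf, velocity_m_per_s = vv),
                           K = 8L, period = period)
      eval_waveform(tmpl, t)
    })
  data.frame(time_s = t, velocity_m_per_s = v)
}

## Per-section perimeter-averaged TAcNO interpolated from an index field
section_tacno <- function(index_field, z_mm) {
  sides <- unique(index_field$side)
  tac <- sapply(sides, function(sd) {
    sub <- index_field[index_field$side == sd, ]
    stats::approx(sub$z_mm, sub$TAcNO, xout = z_mm, rule = 2)$y
  })
  if (is.null(dim(tac))) tac else rowMeans(tac)
}

#' Generate an ILT map statistically tied to a computed NO field
#'
#' Draws per-section thrombus areas from the linear model
#' `area = max(0, alpha + beta * TAcNO + eps)`, `eps ~ N(0, sigma^2)`,
#' with `beta < 0` emulating the observed negative thrombus-area / NO
#' relationship, then distributes each section's area over wall
#' directions (uniformly for the `annular` model; entirely on the
#' section's lowest-TAcNO direction for `one-sided`) by inverting the
#' annular-sector area formula. The noiseless table is returned alongside
#' for recovery tests.
#'
#' @param index_field a [compute_indices()] result with `TAcNO`
#' @param geom the [vessel_geometry()]
#' @param beta coupling slope (mm^2 per nM); negative in the physiological
#'   regime — a warning is issued otherwise unless
#'   `expect_negative = FALSE`
#' @param sigma noise standard deviation (mm^2); alternatively give
#'   `target_r2` to derive it
#' @param target_r2 desired expected R^2; translated into
#'   `sigma = |beta| sd(TAcNO) sqrt((1 - R2)/R2)` over the noiseless ILT
#'   sections
#' @param alpha intercept (mm^2), or `"auto"`: `-beta` times the 75th
#'   percentile of section TAcNO, so roughly three quarters of the
#'   sections carry thrombus
#' @param model `"annular"`, `"one-sided"`, or `"none"`
#' @param spacing section spacing (m)
#' @param seed RNG seed fixing the noise draw
#' @param expect_negative warn when `beta >= 0`
#' @return list: `ilt` (an [ilt_map()]), `truth` (data.frame `z_mm`,
#'   `TAcNO`, `area_true_mm2`, `area_drawn_mm2`), `alpha`, `sigma`
#' @export
make_ilt_from_no <- function(index_field, geom, beta = -40,
                             sigma = NULL, target_r2 = 0.8,
                             alpha = "auto",
                             model = c("one-sided", "annular", "none"),
                             spacing = 5e-3, seed = 1L,
                             expect_negative = TRUE) {
  model <- match.arg(model)
  z <- seq(0, geom$axial_length + 1e-12, by = spacing)
  z_mm <- z * 1e3
  sides <- unique(index_field$side)
  dirs <- if (length(sides) > 1) c("upper", "lower") else "outer"
  if (model == "none") {
    H <- matrix(0, length(z), length(dirs))
    return(list(ilt = ilt_map(z, H, dirs),
                truth = data.frame(z_mm = z_mm, TAcNO = section_tacno(index_field, z_mm),
                                   area_true_mm2 = 0, area_drawn_mm2 = 0),
                alpha = 0, sigma = 0))
  }
  if (beta >= 0 && expect_negative)
    warning("beta >= 0: thrombus area set to increase with NO, outside the physiological regime")
  tac <- section_tacno(index_field, z_mm)
  auto_alpha <- identical(alpha, "auto")
  if (auto_alpha) alpha <- -beta * unname(stats::quantile(tac, 0.75))
  if (is.null(sigma)) {
    if (target_r2 <= 0 || target_r2 > 1) stop("target_r2 must be in (0, 1]")
    sig_sd <- stats::sd(beta * tac[alpha + beta * tac > 0])
    sigma <- if (target_r2 == 1) 0 else sig_sd * sqrt((1 - target_r2) / target_r2)
  }
  ## auto intercept: one noise standard deviation of margin above the
  ## truncation boundary, so generated ILT sections carry clearly positive
  ## burden (as in the observed per-section scatter) while the highest-NO
  ## sections stay thrombus-free; without the margin, zero-truncation of
  ## boundary sections visibly attenuates slope recovery
  if (auto_alpha) alpha <- alpha + sigma
  area_true <- pmax(0, alpha + beta * tac)
  set.seed(seed)
  eps <- stats::rnorm(length(z), 0, sigma)
  area <- pmax(0, alpha + beta * tac + eps)

  ## per-side TAcNO to pick the low-NO direction in the one-sided model
  tac_side <- sapply(sides, function(sd) {
    sub <- index_field[index_field$side == sd, ]
    stats::approx(sub$z_mm, sub$TAcNO, xout = z_mm, rule = 2)$y
  })
  nd <- length(dirs)
  H <- matrix(0, length(z), nd, dimnames = list(NULL, dirs))
  for (k in seq_along(z)) {
    A <- area[k] * 1e-6          # mm^2 -> m^2
    if (A <= 0) next
    if (model == "annular") {
      for (d in dirs) {
        r <- radius_profile(geom, min(z[k], geom$axial_length),
                            radius_side_for(d))
        H[k, d] <- sqrt(r^2 + A / pi) - r
      }
    } else {
      dsel <- if (nd == 1) dirs else {
        ts <- if (is.null(dim(tac_side))) tac_side[k] else tac_side[k, ]
        side_low <- sides[which.min(ts)]
        if (side_low == "bottom") "lower" else "upper"
      }
      r <- radius_profile(geom, min(z[k], geom$axial_length),
                          radius_side_for(dsel))
      H[k, dsel] <- sqrt(r^2 + nd * A / pi) - r
    }
  }
  list(ilt = ilt_map(z, H, dirs),
       truth = data.frame(z_mm = z_mm, TAcNO = tac,
                          area_true_mm2 = area_true, area_drawn_mm2 = area),
       alpha = alpha, sigma = sigma)
}

#' Default synthetic-study configuration
#'
#' Nested configuration describing a full synthetic study: an
#' asymmetrically bulged fusiform segment (60 mm long, 10 mm inlet
#' radius, 7 mm bulge with asymmetry 0.6, giving 13 cross-sections at the
#' 5 mm spacing), a triphasic aortic inlet waveform (period 1 s, systolic
#' peak 0.5 m/s), the published fluid/transport constants, the 5-cycle /
#' 5 mm / 20 mm analysis protocol, and a one-sided ILT model coupled to
#' TAcNO with slope -40 mm^2/nM and noise set for an expected R^2 of 0.8.
#'
#' @param seed study seed
#' @return nested list of class `run_config`
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    study = list(seed = as.integer(seed)),
    geometry = list(axial_length_mm = 60, inlet_radius_mm = 10,
                    bulge_amplitude_mm = 7, bulge_center_mm = 30,
                    bulge_width_mm = 10, asymmetry = 0.6,
                    wall_thickness_mm = 2),
    fluid = list(density = 1056, viscosity = 0.0035),
    transport = list(Dl = 3.3e-9, koxgen = 7.56e-6, kery = 2.3,
                     Dw = 8.48e-10, kw = 0.01,
                     Rbasal = 2.13, Rmax = 457.5, b = 3.5,
                     delta_en = 2.5e-6),
    solver = list(mode = "planar-2D", nz = 57L, nr = 33L, nw = 11L,
                  grading_ratio = 1.15, cycles = 5L,
                  steps_per_cycle = 200L, theta = 0.5),
    waveform = list(preset = "triphasic-aortic", period_s = 1.0,
                    peak_velocity = 0.5, harmonics = 8L, samples = 64L),
    ilt = list(model = "one-sided", beta_mm2_per_nM = -40,
               alpha = "auto", target_r2 = 0.8),
    analysis = list(section_spacing_mm = 5, representative_spacing_mm = 20,
                    line_fraction = 1.0)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Structural and physical checks (positivity of fluid/transport/geometry
#' constants, supported mode and preset, consistency of asymmetry with
#' the mesh mode). Errors are raised before any computation.
#'
#' @param cfg a configuration list (see [default_config()])
#' @return the validated config, invisibly
#' @export
validate_config <- function(cfg) {
  need <- c("study", "geometry", "fluid", "transport", "solver",
            "waveform", "ilt", "analysis")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing block(s): ", paste(miss, collapse = ", "))
  g <- cfg$geometry
  if (g$axial_length_mm <= 0 || g$inlet_radius_mm <= 0 || g$wall_thickness_mm <= 0)
    stop("geometry lengths must be positive")
  if (g$asymmetry < 0 || g$asymmetry > 1) stop("asymmetry must lie in [0, 1]")
  if (cfg$fluid$density <= 0 || cfg$fluid$viscosity <= 0)
    stop("fluid density and viscosity must be positive")
  if (any(unlist(cfg$transport) <= 0)) stop("transport constants must be positive")
  if (!cfg$solver$mode %in% c("axisymmetric-2D", "planar-2D"))
    stop("unsupported solver mode: ", cfg$solver$mode)
  if (cfg$solver$mode == "axisymmetric-2D" && g$asymmetry > 0)
    stop("axisymmetric mode cannot represent an asymmetric bulge")
  if (!cfg$waveform$preset %in% c("triphasic-aortic", "sinusoidal", "constant"))
    stop("unsupported waveform preset: ", cfg$waveform$preset)
  if (!cfg$ilt$model %in% c("one-sided", "annular", "none"))
    stop("unsupported ilt model: ", cfg$ilt$model)
  if (cfg$solver$cycles < 1) stop("solver cycles must be >= 1")
  invisible(cfg)
}

#' Build the geometry / mesh described by a configuration
#' @param cfg a [default_config()]-style configuration
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry
  vessel_geometry(axial_length = g$axial_length_mm * 1e-3,
                  inlet_radius = g$inlet_radius_mm * 1e-3,
                  bulge_amplitude = g$bulge_amplitude_mm * 1e-3,
                  bulge_center = g$bulge_center_mm * 1e-3,
                  bulge_width = g$bulge_width_mm * 1e-3,
                  asymmetry = g$asymmetry,
                  wall_thickness = g$wall_thickness_mm * 1e-3)
}

#' @rdname config_geometry
#' @export
config_mesh <- function(cfg) {
  build_mesh(config_geometry(cfg),
             resolution = list(nz = cfg$solver$nz, nr = cfg$solver$nr,
                               nw = cfg$solver$nw),
             mode = cfg$solver$mode,
             grading_ratio = cfg$solver$grading_ratio)
}

#' Generate a self-contained synthetic study directory
#'
#' Writes the resolved configuration, the inlet waveform samples, and —
#' unless the ILT model is `none` — an ILT map coupled to the study's own
#' computed NO field (which requires running the flow, NO-transport and
#' index stages once at the configured resolution; their outputs are also
#' written, so the directory is immediately analyzable). A README
#' manifest records the seed and package version.
#'
#' @param config a [default_config()]-style configuration
#' @param dir target directory (created if needed)
#' @param quiet suppress progress
#' @return the directory path, invisibly
#' @export
make_study <- function(config = default_config(), dir, quiet = TRUE) {
  validate_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(dir, "config.yaml"))
  wf_samples <- make_waveform(config$waveform$preset,
                              period = config$waveform$period_s,
                              peak_velocity = config$waveform$peak_velocity,
                              n = config$waveform$samples)
  utils::write.csv(wf_samples, file.path(dir, "waveform.csv"),
                   row.names = FALSE)
  writeLines(c("# Synthetic study bundle",
               "",
               sprintf("- seed: %d", config$study$seed),
               sprintf("- package: aneuNO %s",
                       as.character(utils::packageVersion("aneuNO"))),
               sprintf("- ilt model: %s", config$ilt$model),
               "",
               "Files: config.yaml, waveform.csv, ilt.csv (when an ILT",
               "model is configured), plus stage outputs under flow/, no/,",
               "indices/ when the generator had to run the model."),
             file.path(dir, "README.md"))
  if (config$ilt$model != "none") {
    ## the coupling needs the study's own TAcNO field: run the stages once
    stage_flow(dir, quiet = quiet)
    stage_no(dir, quiet = quiet)
    stage_indices(dir, quiet = quiet)
    idx <- utils::read.csv(file.path(dir, "indices", "indices.csv"))
    geom <- config_geometry(config)
    gen <- make_ilt_from_no(idx, geom,
                            beta = config$ilt$beta_mm2_per_nM,
                            target_r2 = config$ilt$target_r2,
                            alpha = config$ilt$alpha,
                            model = config$ilt$model,
                            spacing = config$analysis$section_spacing_mm * 1e-3,
                            seed = config$study$seed)
    write_ilt_csv(gen$ilt, file.path(dir, "ilt.csv"))
    utils::write.csv(gen$truth, file.path(dir, "ilt_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
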