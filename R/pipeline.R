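## Pipeline stages over a study directory. Each stage reads its
## predecessors' outputs from the directory, computes, and writes both a
## machine handoff (.rds, runtime artifact) and the CSV/VTK interchange
## files. Stage timing and solver notes go to <stage>/stage_log.json.

stage_paths <- function(dir) {
  list(config = file.path(dir, "config.yaml"),
       waveform = file.path(dir, "waveform.csv"),
       ilt = file.path(dir, "ilt.csv"),
       flow_rds = file.path(dir, "flow", "flow_solution.rds"),
       wss_csv = file.path(dir, "flow", "wss.csv"),
       flow_vtk = file.path(dir, "flow", "flow_field.vtk"),
       no_rds = file.path(dir, "no", "no_solution.rds"),
       no_surface = file.path(dir, "no", "no_surface.csv"),
       no_vtk = file.path(dir, "no", "no_field.vtk"),
       indices = file.path(dir, "indices", "indices.csv"),
       sections = file.path(dir, "analysis", "sections.csv"),
       fit = file.path(dir, "analysis", "fit.json"),
       groups = file.path(dir, "analysis", "groups.json"),
       directional = file.path(dir, "analysis", "directional.json"),
       scatter = file.path(dir, "analysis", "scatter.pdf"))
}

require_input <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing input '%s': run the '%s' stage first",
                 path, producer), call. = FALSE)
  path
}

write_stage_log <- function(dir, stage, started, notes = list()) {
  log <- c(list(stage = stage,
                started = format(started, "%Y-%m-%d %H:%M:%S"),
                elapsed_s = round(as.numeric(Sys.time() - started, units = "secs"), 2)),
           notes)
  dir.create(file.path(dir, stage), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(log, file.path(dir, stage, "stage_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline stages
#'
#' Each stage operates on a study directory: `stage_generate` writes a
#' synthetic study ([make_study()]); `stage_flow` fits the inlet waveform
#' and solves pulsatile flow; `stage_no` solves NO transport driven by
#' the flow; `stage_indices` computes the wall index field;
#' `stage_analyze` runs the sectioning, correlation, group and
#' directional analyses. `run_study` chains flow through analyze.
#'
#' @param dir study directory
#' @param config configuration for `stage_generate` (default
#'   [default_config()])
#' @param quiet suppress progress
#' @return the directory (generate) or the stage's main result object,
#'   invisibly
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
stage_generate <- function(dir, config = default_config(), quiet = TRUE) {
  started <- Sys.time()
  make_study(config, dir, quiet = quiet)
  write_stage_log(dir, "generate", started,
                  list(seed = config$study$seed, ilt_model = config$ilt$model))
  invisible(dir)
}

#' @rdname pipeline
#' @export
stage_flow <- function(dir, quiet = TRUE) {
  started <- Sys.time()
  p <- stage_paths(dir)
  cfg <- read_config(require_input(p$config, "generate"))
  samples <- read_waveform_csv(require_input(p$waveform, "generate"))
  wf <- fit_waveform(samples, K = cfg$waveform$harmonics,
                     period = cfg$waveform$period_s)
  mesh <- config_mesh(cfg)
  props <- fluid_properties(cfg$fluid$density, cfg$fluid$viscosity)
  flow <- solve_pulsatile(mesh, props, wf,
                          cycles = cfg$solver$cycles,
                          steps_per_cycle = cfg$solver$steps_per_cycle,
                          theta = cfg$solver$theta, quiet = quiet)
  dir.create(file.path(dir, "flow"), recursive = TRUE, showWarnings = FALSE)
  saveRDS(flow, p$flow_rds)
  write_wss_csv(extract_wss(flow), p$wss_csv)
  vel <- flow_velocity(flow)
  write_vtk_mesh(mesh, p$flow_vtk,
                 point_data = list(
                   psi = c(flow$psi[, ncol(flow$psi)],
                           rep(0, length(mesh$walls) * mesh$nz * mesh$nw)),
                   uz = c(as.vector(vel$uz),
                          rep(0, length(mesh$walls) * mesh$nz * mesh$nw))))
  write_stage_log(dir, "flow", started,
                  list(waveform_rms = wf$residual_rms,
                       cycles = cfg$solver$cycles,
                       steps_per_cycle = cfg$solver$steps_per_cycle))
  invisible(flow)
}

#' @rdname pipeline
#' @export
stage_no <- function(dir, quiet = TRUE) {
  started <- Sys.time()
  p <- stage_paths(dir)
  cfg <- read_config(require_input(p$config, "generate"))
  flow <- readRDS(require_input(p$flow_rds, "flow"))
  params <- do.call(transport_params, cfg$transport)
  no <- solve_no(flow$mesh, flow, params, cycles = cfg$solver$cycles,
                 quiet = quiet)
  dir.create(file.path(dir, "no"), recursive = TRUE, showWarnings = FALSE)
  saveRDS(no, p$no_rds)
  ## endothelial surface concentrations, time-averaged + final snapshot
  surf <- do.call(rbind, lapply(names(no$cs), function(sd) {
    cs <- no$cs[[sd]]
    tavg <- if (ncol(cs) == 1L) cs[, 1]
    else apply(cs, 1, trapz, x = no$times) / diff(range(no$times))
    data.frame(side = sd,
               z_mm = no$fvg$walls[[sd]]$iface$mz * 1e3,
               tacno_nM = tavg, c_final_nM = cs[, ncol(cs)])
  }))
  utils::write.csv(surf, p$no_surface, row.names = FALSE)
  ## cell-level concentrations: final snapshot and cycle time-average
  tmean <- function(m) if (ncol(m) == 1L) m[, 1]
    else apply(m, 1, trapz, x = no$times) / diff(range(no$times))
  cells <- data.frame(domain = "lumen",
                      z_mm = as.vector(no$fvg$lumen_center$z) * 1e3,
                      y_mm = as.vector(no$fvg$lumen_center$y) * 1e3,
                      c_final_nM = no$cl[, ncol(no$cl)],
                      c_tavg_nM = tmean(no$cl))
  for (sd in names(no$cw)) {
    wc <- no$fvg$walls[[sd]]$center
    cells <- rbind(cells, data.frame(domain = paste0("wall_", sd),
                                     z_mm = as.vector(wc$z) * 1e3,
                                     y_mm = as.vector(wc$y) * 1e3,
                                     c_final_nM = no$cw[[sd]][, ncol(no$cw[[sd]])],
                                     c_tavg_nM = tmean(no$cw[[sd]])))
  }
  utils::write.csv(cells, file.path(dir, "no", "no_cells.csv"),
                   row.names = FALSE)
  nwall <- length(flow$mesh$walls)
  cl_fin <- no$cl[, ncol(no$cl)]
  cw_fin <- unlist(lapply(no$cw, function(m) m[, ncol(m)]))
  write_vtk_mesh(flow$mesh, p$no_vtk,
                 cell_data = list(c_nM = c(cl_fin, cw_fin)))
  write_stage_log(dir, "no", started,
                  list(min_cl = min(no$cl), max_cs = max(unlist(no$cs))))
  invisible(no)
}

#' @rdname pipeline
#' @export
stage_indices <- function(dir, quiet = TRUE) {
  started <- Sys.time()
  p <- stage_paths(dir)
  flow <- readRDS(require_input(p$flow_rds, "flow"))
  no <- readRDS(require_input(p$no_rds, "no"))
  idx <- compute_indices(flow, no)
  dir.create(file.path(dir, "indices"), recursive = TRUE, showWarnings = FALSE)
  write_index_csv(idx, p$indices)
  write_stage_log(dir, "indices", started)
  invisible(idx)
}

#' @rdname pipeline
#' @export
stage_analyze <- function(dir, quiet = TRUE) {
  started <- Sys.time()
  p <- stage_paths(dir)
  cfg <- read_config(require_input(p$config, "generate"))
  dir.create(file.path(dir, "analysis"), recursive = TRUE, showWarnings = FALSE)
  spacing <- cfg$analysis$section_spacing_mm * 1e-3

  if (!file.exists(p$ilt) || cfg$ilt$model == "none") {
    jsonlite::write_json(list(status = "not-applicable",
                              reason = "no ILT map in this study"),
                         p$fit, auto_unbox = TRUE)
    write_stage_log(dir, "analysis", started,
                    list(status = "not-applicable"))
    return(invisible(NULL))
  }
  idx <- utils::read.csv(require_input(p$indices, "indices"))
  geom <- config_geometry(cfg)
  ilt <- read_ilt_csv(p$ilt)
  tab <- build_section_table(geom, ilt, idx, spacing)
  utils::write.csv(as.data.frame(tab), p$sections, row.names = FALSE)

  fit <- tryCatch(correlate_area_no(tab), error = function(e)
    list(status = "not-applicable", reason = conditionMessage(e)))
  jsonlite::write_json(unclass(fit), p$fit, auto_unbox = TRUE, digits = NA)

  grp <- compare_ilt_groups(tab)
  jsonlite::write_json(grp, p$groups, auto_unbox = TRUE, digits = NA)

  dirn <- tryCatch({
    no <- readRDS(require_input(p$no_rds, "no"))
    da <- directional_analysis(no, geom, ilt)
    list(status = "ok",
         mean_tacno_thickest = da$mean_tacno_thickest,
         mean_tacno_thinnest = da$mean_tacno_thinnest,
         per_section = da$per_section)
  }, error = function(e) list(status = "not-applicable",
                              reason = conditionMessage(e)))
  jsonlite::write_json(dirn, p$directional, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  grDevices::pdf(p$scatter, width = 5, height = 4)
  sub <- tab[tab$group == "ILT", ]
  graphics::plot(sub$TAcNO, sub$area_mm2, pch = 19,
                 xlab = "surface-averaged TAcNO (nM)",
                 ylab = "thrombus area (mm^2)",
                 main = "ILT cross-sections")
  graphics::text(sub$TAcNO, sub$area_mm2, labels = round(sub$z_mm),
                 pos = 3, cex = 0.6)
  if (is.null(fit$status))
    graphics::abline(fit$intercept, fit$slope, col = "red")
  grDevices::dev.off()

  write_stage_log(dir, "analysis", started,
                  list(n_ilt = sum(tab$group == "ILT")))
  invisible(list(sections = tab, fit = fit, groups = grp,
                 directional = dirn))
}

#' @rdname pipeline
#' @export
run_study <- function(dir, config = NULL, quiet = TRUE) {
  if (!is.null(config)) stage_generate(dir, config, quiet = quiet)
  stage_flow(dir, quiet = quiet)
  stage_no(dir, quiet = quiet)
  stage_indices(dir, quiet = quiet)
  stage_analyze(dir, quiet = quiet)
}
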