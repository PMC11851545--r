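## File I/O: YAML configuration, CSV interchange formats, legacy VTK
## export. SI units internally; mm/nM at the CSV boundaries, with units in
## the column names.

#' Write / read a run configuration (YAML)
#' @param cfg a configuration list ([default_config()])
#' @param path file path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Read an inlet waveform CSV
#'
#' Two mandatory header columns: `time_s`, `velocity_m_per_s`.
#' @param path CSV path
#' @return data.frame of samples
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "velocity_m_per_s") %in% names(df)))
    stop("waveform CSV must have header columns time_s, velocity_m_per_s")
  df
}

#' Write / read an ILT thickness map CSV
#'
#' Long format: `z_mm`, `direction_label`, `thickness_mm`.
#' @param ilt an [ilt_map()]
#' @param path CSV path
#' @export
write_ilt_csv <- function(ilt, path) {
  df <- do.call(rbind, lapply(ilt$directions, function(d)
    data.frame(z_mm = ilt$z * 1e3, direction_label = d,
               thickness_mm = ilt$thickness[, d] * 1e3)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ilt_csv
#' @export
read_ilt_csv <- function(path) {
  if (!file.exists(path)) stop("ILT file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("z_mm", "direction_label", "thickness_mm") %in% names(df)))
    stop("ILT CSV must have header columns z_mm, direction_label, thickness_mm")
  dirs <- unique(df$direction_label)
  z <- sort(unique(df$z_mm)) * 1e-3
  H <- sapply(dirs, function(d) {
    sub <- df[df$direction_label == d, ]
    sub$thickness_mm[order(sub$z_mm)] * 1e-3
  })
  ilt_map(z, as.matrix(H), dirs)
}

#' Write a WSS series CSV (positions by times)
#'
#' One file per wall side: first columns `side`, `s_mm`, `z_mm`, then one
#' `tau_t<k>_Pa` column per retained time sample.
#' @param wss a [extract_wss()] result
#' @param path CSV path
#' @export
write_wss_csv <- function(wss, path) {
  out <- do.call(rbind, lapply(names(wss$sides), function(nm) {
    sd <- wss$sides[[nm]]
    tau <- as.data.frame(sd$tau)
    names(tau) <- sprintf("tau_t%03d_Pa", seq_len(ncol(tau)))
    cbind(data.frame(side = nm, s_mm = sd$s * 1e3), tau)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an index field CSV
#' @param idx a [compute_indices()] result
#' @param path CSV path
#' @export
write_index_csv <- function(idx, path) {
  utils::write.csv(as.data.frame(idx), path, row.names = FALSE)
  invisible(path)
}

## ---- legacy VTK (ASCII, unstructured grid of quads) -------------------

vtk_block_cells <- function(nz, nj, offset) {
  i <- rep(seq_len(nz - 1L), nj - 1L)
  j <- rep(seq_len(nj - 1L), each = nz - 1L)
  id <- function(ii, jj) offset + (jj - 1L) * nz + ii - 1L  # 0-based
  cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
}

#' Export a mesh (with optional fields) as legacy VTK
#'
#' Writes the lumen block and all wall bands as an ASCII legacy VTK
#' unstructured grid of quadrilaterals, with a `domain` cell field
#' (0 = lumen, 1 = wall) and any supplied point/cell fields.
#'
#' @param mesh a `vessel_mesh`
#' @param path output file (conventionally `.vtk`)
#' @param point_data named list of per-node vectors (lumen nodes first,
#'   then wall nodes per side)
#' @param cell_data named list of per-cell vectors (lumen cells first,
#'   then wall cells per side)
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list(), cell_data = list()) {
  pts <- cbind(as.vector(mesh$Z), as.vector(mesh$Y))
  cells <- vtk_block_cells(mesh$nz, mesh$nr, 0L)
  dom <- rep(0L, nrow(cells))
  off <- nrow(pts)
  for (sd in names(mesh$walls)) {
    w <- mesh$walls[[sd]]
    pts <- rbind(pts, cbind(as.vector(w$Z), as.vector(w$Y)))
    wc <- vtk_block_cells(mesh$nz, mesh$nw, off)
    cells <- rbind(cells, wc)
    dom <- c(dom, rep(1L, nrow(wc)))
    off <- nrow(pts)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuNO mesh export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(cbind(pts, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(cells), 5L * nrow(cells)), con)
  utils::write.table(cbind(4L, cells), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
  writeLines(as.character(rep(9L, nrow(cells))), con)   # VTK_QUAD
  writeLines(sprintf("CELL_DATA %d", nrow(cells)), con)
  writeLines(c("SCALARS domain int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(dom), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 10), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}
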