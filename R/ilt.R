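## Sectioning, thrombus-area and correlation protocol linking intraluminal
## thrombus (ILT) geometry to NO concentration.

ILT_LABEL_THRESHOLD_M <- 1e-4   # 0.1 mm: a section is "ILT" above this

#' Intraluminal thrombus thickness map
#'
#' Thrombus thickness over the wall, resolved by axial position and wall
#' direction. Directions follow the mesh wall sides (`outer` for
#' axisymmetric, `upper`/`lower` for planar geometries); any label set is
#' accepted so a four-direction (anterior/posterior/inner/outer) map can
#' be represented as well.
#'
#' @param z axial positions (m), strictly increasing
#' @param thickness matrix `length(z) x n_directions` of thicknesses (m),
#'   or a vector for a single direction
#' @param directions direction labels (column names)
#' @return object of class `ilt_map`
#' @export
ilt_map <- function(z, thickness, directions = colnames(thickness)) {
  thickness <- as.matrix(thickness)
  if (is.null(directions)) directions <- paste0("dir", seq_len(ncol(thickness)))
  if (length(z) != nrow(thickness)) stop("z and thickness rows must match")
  if (any(diff(z) <= 0)) stop("z must be strictly increasing")
  if (any(thickness < 0)) stop("thrombus thickness must be non-negative")
  colnames(thickness) <- directions
  structure(list(z = z, thickness = thickness, directions = directions),
            class = "ilt_map")
}

#' @export
print.ilt_map <- function(x, ...) {
  cat(sprintf("<ilt_map> %d axial stations x %d direction(s) [%s]; max %.2f mm\n",
              length(x$z), length(x$directions),
              paste(x$directions, collapse = ", "), 1e3 * max(x$thickness)))
  invisible(x)
}

## Interpolated thickness at z for one direction (m)
ilt_thickness <- function(ilt, z, direction) {
  if (any(z < min(ilt$z) - 1e-9 | z > max(ilt$z) + 1e-9))
    stop("ILT map does not cover the requested axial positions")
  stats::approx(ilt$z, ilt$thickness[, direction], xout = z, rule = 2)$y
}

## Side label -> radius profile side for the idealized geometry
radius_side_for <- function(direction) {
  if (direction %in% c("upper", "lower")) direction else "mean"
}

#' Cross-section skeleton: positions and ILT / non-ILT labels
#'
#' Sections are taken every `spacing` (5 mm by default) from the segment
#' inlet; a section is labelled `ILT` when any direction's interpolated
#' thickness exceeds 0.1 mm there (a tolerance against numerical noise in
#' generated maps, rather than strictly positive thickness).
#'
#' @param geom a [vessel_geometry()]
#' @param ilt an [ilt_map()] covering the segment
#' @param spacing section spacing (m); default 5 mm
#' @return data.frame: `z_m`, `z_mm`, `group`
#' @export
section_geometry <- function(geom, ilt, spacing = 5e-3) {
  if (spacing <= 0 || spacing > geom$axial_length)
    stop("section spacing must be positive and no larger than the segment")
  z <- seq(0, geom$axial_length + 1e-12, by = spacing)
  hmax <- apply(sapply(ilt$directions, function(d) ilt_thickness(ilt, z, d)),
                1, max)
  data.frame(z_m = z, z_mm = z * 1e3,
             group = ifelse(hmax > ILT_LABEL_THRESHOLD_M, "ILT", "non-ILT"))
}

#' Thrombus cross-sectional area at a section
#'
#' For the idealized geometry each direction contributes an annular sector
#' between the lumen contour and the thrombus-free contour: with `n`
#' directions each spanning `2 pi / n`, the area is
#' \eqn{\sum_d (\pi/n)\,[(r_d + h_d)^2 - r_d^2]}, which reduces to the
#' full annulus \eqn{\pi[(r+h)^2 - r^2]} for a uniform single-direction
#' map.
#'
#' @param z section position (m)
#' @param geom a [vessel_geometry()]
#' @param ilt an [ilt_map()]
#' @return thrombus area in mm^2
#' @export
thrombus_area <- function(z, geom, ilt) {
  if (z < 0 || z > geom$axial_length) stop("section outside the segment")
  nd <- length(ilt$directions)
  a <- 0
  for (d in ilt$directions) {
    h <- ilt_thickness(ilt, z, d)
    r <- radius_profile(geom, z, radius_side_for(d))
    if (h > r) stop("thrombus thickness exceeds the local lumen radius (data error)")
    a <- a + (pi / nd) * ((r + h)^2 - r^2)
  }
  a * 1e6     # m^2 -> mm^2
}

#' Assemble the full section table
#'
#' Combines [section_geometry()] labels, [thrombus_area()] and the
#' per-section surface-averaged TAcNO interpolated from an index field
#' (perimeter average across wall sides at each section).
#'
#' @param geom a [vessel_geometry()]
#' @param ilt an [ilt_map()]
#' @param index_field a [compute_indices()] result with `TAcNO` filled
#' @param spacing section spacing (m)
#' @return `section_table` data.frame: `z_m`, `z_mm`, `group`,
#'   `area_mm2`, `TAcNO`
#' @export
build_section_table <- function(geom, ilt, index_field, spacing = 5e-3) {
  sk <- section_geometry(geom, ilt, spacing)
  sk$area_mm2 <- vapply(sk$z_m, thrombus_area, 0, geom = geom, ilt = ilt)
  sides <- unique(index_field$side)
  tac <- sapply(sides, function(sd) {
    sub <- index_field[index_field$side == sd, ]
    stats::approx(sub$z_mm, sub$TAcNO, xout = sk$z_mm, rule = 2)$y
  })
  sk$TAcNO <- if (is.null(dim(tac))) tac else rowMeans(tac)
  class(sk) <- c("section_table", "data.frame")
  sk
}

#' Least-squares correlation of thrombus area against TAcNO
#'
#' Ordinary least squares of per-section thrombus area (mm^2) on
#' per-section surface-averaged TAcNO (nM), restricted to ILT sections by
#' default, with the regression F test of goodness of fit.
#'
#' @param table a [build_section_table()] result (columns `TAcNO`,
#'   `area_mm2`, `group`), or any data.frame with those columns
#' @param ilt_only restrict to sections labelled `ILT`
#' @return object of class `fit_result`: `slope` (mm^2 per nM),
#'   `intercept`, `r_squared`, `f_statistic`, `p_value`, `n`
#' @export
correlate_area_no <- function(table, ilt_only = TRUE) {
  df <- as.data.frame(table)
  if (ilt_only) df <- df[df$group == "ILT", ]
  if (nrow(df) < 3L) stop("need at least 3 sections for the correlation")
  if (stats::var(df$TAcNO) <= 0)
    stop("degenerate TAcNO variance: correlation undefined")
  if (stats::var(df$area_mm2) == 0) {
    ## constant response: no explainable variance (summary.lm would
    ## return 0/0 noise here)
    return(structure(list(slope = 0, intercept = df$area_mm2[1],
                          r_squared = 0, f_statistic = 0, p_value = 1,
                          n = nrow(df)),
                     class = "fit_result"))
  }
  fit <- stats::lm(area_mm2 ~ TAcNO, data = df)
  sm <- suppressWarnings(summary(fit))   # exact fits warn harmlessly
  r2 <- sm$r.squared
  if (!is.null(sm$fstatistic)) {
    F <- unname(sm$fstatistic[1])
    p <- stats::pf(F, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  } else { F <- 0; p <- 1 }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, f_statistic = F, p_value = unname(p),
                 n = nrow(df)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> area = %.4g %+.4g * TAcNO (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  R^2 = %.4f, F = %.3g, p = %.3g\n",
              x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}

#' Compare surface-averaged TAcNO between ILT and non-ILT sections
#'
#' @param table a [build_section_table()] result
#' @return list: group means, their difference (`non-ILT` minus `ILT`),
#'   group sizes, and a `complete` flag (FALSE when one group is empty)
#' @export
compare_ilt_groups <- function(table) {
  df <- as.data.frame(table)
  m_ilt <- mean(df$TAcNO[df$group == "ILT"])
  m_non <- mean(df$TAcNO[df$group == "non-ILT"])
  n_ilt <- sum(df$group == "ILT"); n_non <- sum(df$group == "non-ILT")
  complete <- n_ilt > 0 && n_non > 0
  if (!complete)
    warning("one section group is empty; returning a partial comparison")
  list(mean_ilt = m_ilt, mean_non_ilt = m_non,
       difference = m_non - m_ilt,
       n_ilt = n_ilt, n_non_ilt = n_non, complete = complete)
}

## Time-averaged lumen concentration along the radial chord from the
## `direction` wall inward to the centerline, at the cell column nearest z
line_averaged_tacno <- function(no_sol, z, direction, line_fraction = 1) {
  if (line_fraction <= 0) stop("zero-length line request")
  fvg <- no_sol$fvg
  mesh <- fvg$mesh
  tavg <- if (ncol(no_sol$cl) == 1L) no_sol$cl[, 1]
  else apply(no_sol$cl, 1, trapz, x = no_sol$times) /
    (no_sol$times[length(no_sol$times)] - no_sol$times[1])
  cz <- fvg$lumen_center$z[, 1]
  i <- which.min(abs(cz - z))
  yc <- fvg$lumen_center$y[i, ]            # transverse cell centres
  y_mid <- mean(range(mesh$Y[i, ]))        # centerline
  jsel <- switch(direction,
                 upper = which(yc >= y_mid),
                 lower = which(yc <= y_mid),
                 outer = seq_along(yc),
                 stop("unknown direction: ", direction))
  ## restrict to the requested chord fraction measured from the wall
  ywall <- if (direction == "lower") min(mesh$Y[i, ]) else max(mesh$Y[i, ])
  depth <- abs(yc[jsel] - ywall)
  max_depth <- abs(y_mid - ywall)
  jsel <- jsel[depth <= line_fraction * max_depth + 1e-12]
  cells <- (jsel - 1L) * fvg$nci + i
  wts <- fvg$Vl[cells]
  stats::weighted.mean(tavg[cells], wts)
}

#' Directional NO / thrombus-thickness analysis on representative sections
#'
#' Takes representative sections (20 mm apart by convention) inside the
#' ILT region, computes the line-averaged TAcNO along each wall
#' direction's radial chord (interface to centerline), identifies the
#' thickest- and thinnest-thrombus directions per section, and averages
#' over sections. Requires a geometry mode with at least two wall
#' directions (planar-2D).
#'
#' @param no_sol a [solve_no()] solution on a planar-2D mesh
#' @param geom the [vessel_geometry()]
#' @param ilt an [ilt_map()] with the mesh's wall directions
#' @param section_z axial positions (m) of the representative sections;
#'   default: three sections 20 mm apart centred on the ILT region
#' @param line_fraction fraction of the radial chord to average over
#' @return list: per-section data.frame (`z_mm`, direction columns of
#'   line-averaged TAcNO, `thickest`, `thinnest`), and the across-section
#'   means `mean_tacno_thickest`, `mean_tacno_thinnest`
#' @export
directional_analysis <- function(no_sol, geom, ilt, section_z = NULL,
                                 line_fraction = 1) {
  fvg <- no_sol$fvg
  dirs <- intersect(ilt$directions, names(fvg$mesh$walls))
  if (length(dirs) < 2L)
    stop("directional analysis needs at least two wall directions (planar-2D mode)")
  if (is.null(section_z)) section_z <- representative_sections(ilt)
  hmax <- sapply(section_z, function(z)
    max(vapply(dirs, function(d) ilt_thickness(ilt, z, d), 0)))
  if (any(hmax <= ILT_LABEL_THRESHOLD_M))
    stop("representative sections must lie inside the ILT region")
  rows <- lapply(section_z, function(z) {
    tac <- vapply(dirs, function(d)
      line_averaged_tacno(no_sol, z, d, line_fraction), 0)
    h <- vapply(dirs, function(d) ilt_thickness(ilt, z, d), 0)
    data.frame(z_mm = z * 1e3, t(tac),
               thickest = dirs[which.max(h)], thinnest = dirs[which.min(h)],
               tacno_thickest = tac[which.max(h)],
               tacno_thinnest = tac[which.min(h)])
  })
  per_section <- do.call(rbind, rows)
  rownames(per_section) <- NULL
  list(per_section = per_section,
       mean_tacno_thickest = mean(per_section$tacno_thickest),
       mean_tacno_thinnest = mean(per_section$tacno_thinnest))
}

#' Representative section positions inside the ILT region
#'
#' Picks `n` sections spaced `spacing` apart (20 mm by default), centred
#' on the ILT support.
#' @param ilt an [ilt_map()]
#' @param spacing spacing between sections (m)
#' @param n number of sections
#' @export
representative_sections <- function(ilt, spacing = 20e-3, n = 3L) {
  hmax_at <- function(z) {
    h <- sapply(ilt$directions, function(d) ilt_thickness(ilt, z, d))
    if (is.null(dim(h))) max(h) else apply(as.matrix(h), 1, max)
  }
  has <- apply(ilt$thickness, 1, max) > ILT_LABEL_THRESHOLD_M
  if (!any(has)) stop("ILT map has no region above the labelling threshold")
  offs <- spacing * (seq_len(n) - (n + 1) / 2)
  ## candidate fan centres on the map's own grid: every section of the fan
  ## must sit on thrombus (the support need not be contiguous)
  centers <- ilt$z[has]
  ok <- vapply(centers, function(zc) {
    zz <- zc + offs
    all(zz >= min(ilt$z), zz <= max(ilt$z)) && all(hmax_at(zz) > ILT_LABEL_THRESHOLD_M)
  }, TRUE)
  if (!any(ok))
    stop(sprintf(
      "no placement of %d sections %.0f mm apart fits inside the ILT region",
      n, 1e3 * spacing))
  score <- vapply(centers[ok], function(zc) sum(hmax_at(zc + offs)), 0)
  centers[ok][which.max(score)] + offs
}
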