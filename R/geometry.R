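#' Parametric two-domain vessel geometry
#'
#' Describes an idealized straight or fusiform-bulged vessel segment as a
#' lumen bounded by an arterial wall of constant thickness. The lumen radius
#' follows a Gaussian bulge profile
#' \deqn{r(z) = R_0 + A \, s \, \exp\{-(z - z_c)^2 / (2 w^2)\}}
#' where the side factor \eqn{s} splits the bulge between the two wall sides:
#' \eqn{s = 1 + \alpha} on the upper side and \eqn{s = 1 - \alpha} on the
#' lower side, with asymmetry \eqn{\alpha \in [0, 1]} (so \eqn{\alpha = 0}
#' is an axisymmetric fusiform dilation and \eqn{\alpha = 1} places the
#' entire bulge on one side). The outer wall is the lumen surface offset
#' outward along the local normal by `wall_thickness`.
#'
#' All lengths are SI metres.
#'
#' @param axial_length segment length (m)
#' @param inlet_radius undilated lumen radius \eqn{R_0} (m)
#' @param bulge_amplitude peak radial dilation \eqn{A} (m); 0 gives a
#'   straight tube
#' @param bulge_center axial position of the bulge peak (m); default mid
#'   segment
#' @param bulge_width Gaussian standard deviation \eqn{w} of the bulge (m)
#' @param asymmetry bulge asymmetry \eqn{\alpha \in [0,1]}
#' @param wall_thickness arterial wall thickness (m); default 2 mm, the
#'   conventional aortic value
#' @return an object of class `vessel_geometry`
#' @examples
#' geom <- vessel_geometry(0.06, 0.01, bulge_amplitude = 0.005)
#' radius_profile(geom, 0.03)
#' @export
vessel_geometry <- function(axial_length,
                            inlet_radius,
                            bulge_amplitude = 0,
                            bulge_center = axial_length / 2,
                            bulge_width = axial_length / 8,
                            asymmetry = 0,
                            wall_thickness = 2e-3) {
  stopifnot(is.numeric(axial_length), length(axial_length) == 1L)
  if (axial_length <= 0) stop("axial_length must be positive")
  if (inlet_radius <= 0) stop("inlet_radius must be positive")
  if (bulge_amplitude < 0) stop("bulge_amplitude must be >= 0")
  if (wall_thickness <= 0) stop("wall_thickness must be positive")
  if (asymmetry < 0 || asymmetry > 1) stop("asymmetry must lie in [0, 1]")
  if (bulge_amplitude > 0 && bulge_width <= 0)
    stop("bulge_width must be positive when a bulge is present")
  geom <- structure(
    list(axial_length = axial_length,
         inlet_radius = inlet_radius,
         bulge_amplitude = bulge_amplitude,
         bulge_center = bulge_center,
         bulge_width = bulge_width,
         asymmetry = asymmetry,
         wall_thickness = wall_thickness),
    class = "vessel_geometry")
  ## r(z) > 0 everywhere: Gaussian bulge only adds radius, but guard anyway
  zs <- seq(0, axial_length, length.out = 101L)
  if (any(radius_profile(geom, zs, side = "lower") <= 0))
    stop("degenerate geometry: lumen radius profile is not positive everywhere")
  geom
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("<vessel_geometry>\n")
  cat(sprintf("  length %.1f mm, inlet radius %.2f mm, wall %.2f mm\n",
              1e3 * x$axial_length, 1e3 * x$inlet_radius,
              1e3 * x$wall_thickness))
  if (x$bulge_amplitude > 0) {
    cat(sprintf("  bulge: amplitude %.2f mm at z = %.1f mm, width %.1f mm, asymmetry %.2f\n",
                1e3 * x$bulge_amplitude, 1e3 * x$bulge_center,
                1e3 * x$bulge_width, x$asymmetry))
  } else cat("  straight tube (no bulge)\n")
  invisible(x)
}

side_factor <- function(geom, side) {
  switch(side,
         upper = 1 + geom$asymmetry,
         lower = 1 - geom$asymmetry,
         outer = ,            # axisymmetric wall label
         mean  = 1,
         stop("unknown wall side: ", side))
}

#' Lumen radius profile
#'
#' Evaluates the lumen radius (distance from the vessel axis to the wall
#' side) at axial positions `z`.
#'
#' @param geom a [vessel_geometry()]
#' @param z axial positions (m), within `[0, axial_length]`
#' @param side `"upper"`, `"lower"`, or `"mean"` (the side-averaged profile,
#'   the only meaningful one for axisymmetric geometries)
#' @param deriv derivative order 0, 1 or 2 with respect to z
#' @return radii (m), or their axial derivatives
#' @export
radius_profile <- function(geom, z, side = "mean", deriv = 0L) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (any(z < -1e-12 | z > geom$axial_length + 1e-12))
    stop("z outside the vessel segment [0, axial_length]")
  s <- side_factor(geom, side)
  if (geom$bulge_amplitude == 0) {
    base <- if (deriv == 0L) geom$inlet_radius else 0
    return(rep(base, length(z)))
  }
  w <- geom$bulge_width
  u <- z - geom$bulge_center
  phi <- exp(-u^2 / (2 * w^2))
  amp <- geom$bulge_amplitude * s
  switch(as.character(deriv),
         "0" = geom$inlet_radius + amp * phi,
         "1" = amp * (-u / w^2) * phi,
         "2" = amp * (u^2 / w^4 - 1 / w^2) * phi,
         stop("deriv must be 0, 1 or 2"))
}

## Smooth analytic grading maps eta(sigma) on [0,1], sigma uniform. The
## stretching strength corresponds to adjacent spacings changing by
## `ratio` at a 25-node reference resolution; it is held fixed under
## refinement so that the C-infinity map keeps finite differences taken
## in sigma second order (a strength tied to n would freeze the
## truncation error). Returns nodes plus the analytic map derivatives
## needed by the mapped operators.
graded_map <- function(n, ratio, cluster = c("end", "both", "start")) {
  cluster <- match.arg(cluster)
  stopifnot(n >= 3L, ratio >= 1)
  sigma <- seq(0, 1, length.out = n)
  if (ratio == 1) {
    return(list(sigma = sigma, x = sigma,
                dx = rep(1, n), d2x = rep(0, n)))
  }
  s <- 24 * log(ratio)
  if (cluster == "end") {
    x   <- 1 - sinh(s * (1 - sigma)) / sinh(s)
    dx  <- s * cosh(s * (1 - sigma)) / sinh(s)
    d2x <- -s^2 * sinh(s * (1 - sigma)) / sinh(s)
  } else if (cluster == "start") {
    x   <- sinh(s * sigma) / sinh(s)
    dx  <- s * cosh(s * sigma) / sinh(s)
    d2x <- s^2 * sinh(s * sigma) / sinh(s)
  } else {
    s <- s / 2
    u <- s * (2 * sigma - 1)
    x   <- 0.5 * (1 + tanh(u) / tanh(s))
    dx  <- s / cosh(u)^2 / tanh(s)
    d2x <- -4 * s^2 * tanh(u) / cosh(u)^2 / tanh(s)
  }
  list(sigma = sigma, x = x, dx = dx, d2x = d2x)
}

graded_coords <- function(n, ratio, cluster = "end") graded_map(n, ratio, cluster)$x

#' Build a structured two-domain mesh
#'
#' Discretizes a [vessel_geometry()] into a boundary-fitted structured grid:
#' a lumen block (axial index by radial fraction) plus one wall band per wall
#' side, offset along the local outer normal so the band spans exactly
#' `wall_thickness`. Near-wall spacing is geometrically graded (default
#' ratio 1.15) to capture the wall shear and concentration boundary layers.
#'
#' Modes:
#' \describe{
#'   \item{`axisymmetric-2D`}{cylindrical (z, r) half-plane; requires
#'     `asymmetry == 0`. One wall band (`outer`).}
#'   \item{`planar-2D`}{planar channel with two distinct wall sides
#'     (`upper`, `lower`), supporting asymmetric bulges.}
#' }
#'
#' @param geom a [vessel_geometry()]
#' @param resolution list with node counts `nz` (axial), `nr` (lumen
#'   radial/transverse), `nw` (wall normal); missing entries take defaults
#' @param mode `"axisymmetric-2D"` or `"planar-2D"`
#' @param grading_ratio geometric near-wall grading ratio (>= 1)
#' @return an object of class `vessel_mesh`
#' @export
build_mesh <- function(geom,
                       resolution = list(),
                       mode = c("axisymmetric-2D", "planar-2D"),
                       grading_ratio = 1.15) {
  stopifnot(inherits(geom, "vessel_geometry"))
  mode <- match.arg(mode)
  if (mode == "axisymmetric-2D" && geom$asymmetry > 0)
    stop("axisymmetric mode cannot represent an asymmetric bulge; use planar-2D")
  res <- utils::modifyList(list(nz = 57L, nr = 33L, nw = 11L), resolution)
  nz <- as.integer(res$nz); nr <- as.integer(res$nr); nw <- as.integer(res$nw)
  if (nz < 5L || nr < 5L || nw < 4L)
    stop("resolution too coarse: need nz >= 5, nr >= 5, nw >= 4")

  z <- seq(0, geom$axial_length, length.out = nz)
  eta_map <- if (mode == "axisymmetric-2D")
    graded_map(nr, grading_ratio, "end")          # fine at the wall (eta=1)
  else
    graded_map(nr, grading_ratio, "both")         # fine at both walls
  eta <- eta_map$x
  eta_w <- graded_coords(nw, grading_ratio, "start")  # fine at the interface

  ## Mapping y = A(z) + eta * B(z)
  if (mode == "axisymmetric-2D") {
    A  <- rep(0, nz); A1 <- A; A2 <- A
    B  <- radius_profile(geom, z, "mean", 0L)
    B1 <- radius_profile(geom, z, "mean", 1L)
    B2 <- radius_profile(geom, z, "mean", 2L)
    sides <- "outer"
  } else {
    rl  <- radius_profile(geom, z, "lower", 0L)
    ru  <- radius_profile(geom, z, "upper", 0L)
    A   <- -rl
    A1  <- -radius_profile(geom, z, "lower", 1L)
    A2  <- -radius_profile(geom, z, "lower", 2L)
    B   <- rl + ru
    B1  <- radius_profile(geom, z, "lower", 1L) + radius_profile(geom, z, "upper", 1L)
    B2  <- radius_profile(geom, z, "lower", 2L) + radius_profile(geom, z, "upper", 2L)
    sides <- c("upper", "lower")
  }
  if (any(B <= 0)) stop("degenerate geometry: non-positive lumen width")

  Z <- matrix(z, nz, nr)
  Y <- outer(A, rep(1, nr)) + outer(B, eta)

  ## Wall bands: interface curve offset along the outer normal
  walls <- lapply(sides, function(sd) {
    if (sd == "outer" || sd == "upper") {
      f  <- A + B                      # interface curve y = f(z)
      fp <- A1 + B1
      nvec <- cbind(-fp, 1) / sqrt(1 + fp^2)   # outward normal (upper)
    } else {
      f  <- A
      fp <- A1
      nvec <- cbind(fp, -1) / sqrt(1 + fp^2)   # outward normal (lower)
    }
    t_w <- geom$wall_thickness
    Zw <- outer(z, rep(1, nw)) + outer(nvec[, 1] * t_w, eta_w)
    Yw <- outer(f, rep(1, nw)) + outer(nvec[, 2] * t_w, eta_w)
    list(side = sd, Z = Zw, Y = Yw, eta_w = eta_w, normal = nvec)
  })
  names(walls) <- sides

  mesh <- structure(
    list(mode = mode, geom = geom, grading_ratio = grading_ratio,
         nz = nz, nr = nr, nw = nw,
         z = z, eta = eta, eta_map = eta_map, eta_w = eta_w,
         A = A, A1 = A1, A2 = A2, B = B, B1 = B1, B2 = B2,
         Z = Z, Y = Y, walls = walls),
    class = "vessel_mesh")
  vols <- lumen_cell_volumes(mesh)
  if (any(vols <= 0)) stop("mesh has non-positive cell volumes")
  mesh
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat("<vessel_mesh>", x$mode, "\n")
  cat(sprintf("  lumen %d x %d nodes, wall band(s) %s x %d nodes\n",
              x$nz, x$nr, paste(names(x$walls), collapse = "/"), x$nw))
  cat(sprintf("  lumen measure %.4g %s (analytic %.4g)\n",
              lumen_measure(x), if (x$mode == "axisymmetric-2D") "m^3" else "m^2",
              analytic_lumen_measure(x$geom, x$mode)))
  invisible(x)
}

#' Refine a mesh
#'
#' Rebuilds the mesh with per-direction node counts scaled by `factor`
#' (counts become `ceiling(factor * n)`), preserving geometry, mode and
#' grading. Used by the grid-independence protocol.
#'
#' @param mesh a `vessel_mesh`
#' @param factor refinement factor (> 1)
#' @return refined `vessel_mesh`
#' @export
refine <- function(mesh, factor) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  if (factor <= 1) stop("refinement factor must be > 1")
  build_mesh(mesh$geom,
             resolution = list(nz = ceiling(factor * mesh$nz),
                               nr = ceiling(factor * mesh$nr),
                               nw = ceiling(factor * mesh$nw)),
             mode = mesh$mode,
             grading_ratio = mesh$grading_ratio)
}

## ---- cell geometry helpers (structured quads) -------------------------

## Shoelace areas of the (nz-1) x (nr-1) quad cells of a coordinate block
quad_cell_areas <- function(Z, Y) {
  ni <- nrow(Z) - 1L; nj <- ncol(Z) - 1L
  i <- seq_len(ni); j <- seq_len(nj)
  x1 <- Z[i, j, drop = FALSE];     y1 <- Y[i, j, drop = FALSE]
  x2 <- Z[i + 1, j, drop = FALSE]; y2 <- Y[i + 1, j, drop = FALSE]
  x3 <- Z[i + 1, j + 1, drop = FALSE]; y3 <- Y[i + 1, j + 1, drop = FALSE]
  x4 <- Z[i, j + 1, drop = FALSE]; y4 <- Y[i, j + 1, drop = FALSE]
  0.5 * ((x1 * y2 - x2 * y1) + (x2 * y3 - x3 * y2) +
         (x3 * y4 - x4 * y3) + (x4 * y1 - x1 * y4))
}

quad_cell_centroid_y <- function(Z, Y) {
  ni <- nrow(Z) - 1L; nj <- ncol(Z) - 1L
  i <- seq_len(ni); j <- seq_len(nj)
  (Y[i, j, drop = FALSE] + Y[i + 1, j, drop = FALSE] +
   Y[i + 1, j + 1, drop = FALSE] + Y[i, j + 1, drop = FALSE]) / 4
}

## Cell volumes of a block: revolved (2*pi*r_bar*A) in axisymmetric mode,
## plain area (unit depth) in planar mode.
block_cell_volumes <- function(Z, Y, mode) {
  a <- quad_cell_areas(Z, Y)
  if (mode == "axisymmetric-2D") 2 * pi * quad_cell_centroid_y(Z, Y) * a else a
}

lumen_cell_volumes <- function(mesh) {
  block_cell_volumes(mesh$Z, mesh$Y, mesh$mode)
}

wall_cell_volumes <- function(mesh, side) {
  w <- mesh$walls[[side]]
  block_cell_volumes(w$Z, w$Y, mesh$mode)
}

#' Total lumen measure of a mesh
#'
#' Sum of lumen cell measures: revolved volume (m^3) in axisymmetric mode,
#' planar area (m^2, unit depth) in planar mode. Compared against
#' [analytic_lumen_measure()] in discretization checks.
#' @param mesh a `vessel_mesh`
#' @export
lumen_measure <- function(mesh) sum(lumen_cell_volumes(mesh))

#' Analytic lumen measure of a geometry
#'
#' Closed-form counterpart of [lumen_measure()]:
#' \eqn{\int \pi r(z)^2 dz} (axisymmetric) or
#' \eqn{\int (r_u(z) + r_l(z)) dz} (planar), using the Gaussian bulge
#' integrals expressed through the normal CDF.
#' @param geom a [vessel_geometry()]
#' @param mode mesh mode
#' @export
analytic_lumen_measure <- function(geom, mode = "axisymmetric-2D") {
  L <- geom$axial_length; R0 <- geom$inlet_radius
  Amp <- geom$bulge_amplitude; zc <- geom$bulge_center; w <- geom$bulge_width
  ## int_0^L exp(-(z-zc)^2/(2 s^2)) dz
  gauss_int <- function(s) {
    if (Amp == 0) return(0)
    s * sqrt(2 * pi) * (stats::pnorm((L - zc) / s) - stats::pnorm((0 - zc) / s))
  }
  if (mode == "axisymmetric-2D") {
    I1 <- gauss_int(w)              # int phi
    I2 <- gauss_int(w / sqrt(2))    # int phi^2 (Gaussian of sd w/sqrt(2))
    pi * (R0^2 * L + 2 * R0 * Amp * I1 + Amp^2 * I2)
  } else {
    ## width = r_u + r_l = 2 R0 + Amp ((1+a) + (1-a)) phi = 2 R0 + 2 Amp phi
    2 * R0 * L + 2 * Amp * gauss_int(w)
  }
}

## Arc length along the interface curve of a wall side (vector per node)
interface_arclength <- function(mesh, side = names(mesh$walls)[1]) {
  w <- mesh$walls[[side]]
  dz <- diff(w$Z[, 1]); dy <- diff(w$Y[, 1])
  c(0, cumsum(sqrt(dz^2 + dy^2)))
}
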