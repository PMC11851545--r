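#' Fluid properties of blood
#'
#' Defaults are the conventional values for blood as an incompressible
#' Newtonian fluid: density 1056 kg/m^3 and dynamic viscosity 0.0035 Pa s.
#'
#' @param density rho_b (kg/m^3)
#' @param viscosity mu_b (Pa s)
#' @export
fluid_properties <- function(density = 1056, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be strictly positive")
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density),
            class = "fluid_properties")
}

solver_error <- function(msg, residuals = NULL) {
  stop(errorCondition(msg, residuals = residuals,
                      class = c("aneuNO_solver_error", "error", "condition")))
}

## Inlet driver: a `waveform` (pulsatile) or a single mean velocity
## (steady). Returns a closure t -> list(u, psi, omega), each nr x length(t),
## the fully developed profile at the inlet station.
inlet_profile_fun <- function(mesh, props, driver) {
  wf <- if (inherits(driver, "waveform")) driver
        else waveform_from_coefficients(1, as.numeric(driver))
  if (mesh$mode == "axisymmetric-2D") {
    R0 <- mesh$B[1]
    function(t) developed_pulsatile_state(mesh$eta, t, wf, props$nu,
                                          "tube", R = R0)
  } else {
    H0 <- mesh$B[1] / 2
    s  <- mesh$Y[1, ] - (mesh$A[1] + H0)
    function(t) developed_pulsatile_state(s, t, wf, props$nu,
                                          "channel", H = H0)
  }
}

## Normal distances from the first two interior gridlines to each wall,
## and the wall radius (for the axisymmetric no-slip closure)
wall_thom_geom <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr
  dist_to <- function(jwall, jint, nvec) {
    d <- cbind(mesh$Z[, jint] - mesh$Z[, jwall],
               mesh$Y[, jint] - mesh$Y[, jwall])
    abs(rowSums(d * nvec))
  }
  out <- list()
  fp <- mesh$A1 + mesh$B1
  nvec <- cbind(-fp, 1) / sqrt(1 + fp^2)
  out$top <- list(a = dist_to(nr, nr - 1L, nvec),
                  b = dist_to(nr, nr - 2L, nvec),
                  y_w = mesh$Y[, nr])
  if (mesh$mode == "planar-2D") {
    fp <- mesh$A1
    nvec <- cbind(fp, -1) / sqrt(1 + fp^2)
    out$bottom <- list(a = dist_to(1L, 2L, nvec),
                       b = dist_to(1L, 3L, nvec),
                       y_w = mesh$Y[, 1])
  }
  out
}

## Second-order no-slip wall-vorticity closure coefficients: with psi ~
## psi_w + (1/2) psi'' s^2 + (1/6) psi''' s^3 into the fluid and dpsi/dn=0
## at the wall, eliminating psi''' from the first two interior gridlines
## gives psi'' = 2 [b^3 (psi1-psi_w) - a^3 (psi2-psi_w)] / (a^2 b^2 (b-a)),
## and omega_w = -psi'' (divided by r_w in the axisymmetric case).
thom_coefficients <- function(tg, axisym) {
  a <- tg$a; b <- tg$b
  D <- a^2 * b^2 * (b - a)
  c1 <- 2 * b^3 / D
  c2 <- -2 * a^3 / D
  if (axisym) { c1 <- c1 / tg$y_w; c2 <- c2 / tg$y_w }
  list(c1 = c1, c2 = c2)
}

## Monolithic (omega, psi) system for one implicit step (idt = 1/dt; use
## idt = 0, theta = 1 for a steady Picard iteration). The Thom no-slip
## closure couples wall vorticity rows to the first interior psi unknowns,
## so there is no wall-vorticity lag.
coupled_step <- function(ops, mesh, thom, vel, nu, idt, theta,
                         omega_old, psi_in, omega_in, psi_top) {
  n <- ops$n; nz <- ops$nz; nr <- ops$nr
  b <- ops$bnd
  Op <- vorticity_rhs_operator(ops, vel, nu)
  Aoo <- Matrix::Diagonal(n, idt) - theta * Op
  rhs_o <- idt * omega_old +
    if (theta < 1) (1 - theta) * as.numeric(Op %*% omega_old) else 0
  ## boundary rows for the omega block
  Aoo <- set_operator_rows(Aoo, b$outlet, ops$DXI_b); rhs_o[b$outlet] <- 0
  Aoo <- set_identity_rows(Aoo, b$inlet);             rhs_o[b$inlet] <- omega_in
  ## no-slip wall rows: omega_w + c1 psi_1 + c2 psi_2 = (c1 + c2) psi_wall
  ij_op <- list(i = integer(0), j = integer(0), x = numeric(0))
  add_wall <- function(rows, int1, int2, cc, psi_wall_val) {
    ij_op$i <<- c(ij_op$i, rows, rows)
    ij_op$j <<- c(ij_op$j, int1, int2)
    ij_op$x <<- c(ij_op$x, cc$c1, cc$c2)
    rhs_o[rows] <<- (cc$c1 + cc$c2) * psi_wall_val
  }
  Aoo <- set_identity_rows(Aoo, b$top)
  add_wall(b$top,
           node_index(1:nz, nr - 1L, nz), node_index(1:nz, nr - 2L, nz),
           thom_coefficients(thom$top, ops$axisym), psi_top)
  if (mesh$mode == "planar-2D") {
    Aoo <- set_identity_rows(Aoo, b$bottom)
    add_wall(b$bottom,
             node_index(1:nz, 2L, nz), node_index(1:nz, 3L, nz),
             thom_coefficients(thom$bottom, FALSE), 0)
  } else {
    Aoo <- set_identity_rows(Aoo, b$bottom); rhs_o[b$bottom] <- 0
  }
  Aop <- Matrix::sparseMatrix(i = ij_op$i, j = ij_op$j, x = ij_op$x,
                              dims = c(n, n))

  ## psi block: E2 psi + y omega = 0 in the interior, Dirichlet/gradient BCs
  App <- ops$E2
  diag_y <- if (ops$axisym) ops$y else rep(1, n)
  rhs_p <- rep(0, n)
  bc_rows <- c(b$outlet, b$bottom, b$top, b$inlet)
  App <- set_operator_rows(App, b$outlet, ops$DXI_b)
  App <- set_identity_rows(App, b$bottom)
  App <- set_identity_rows(App, b$top)
  App <- set_identity_rows(App, b$inlet)
  keep <- rep(1, n); keep[bc_rows] <- 0
  Apo <- Matrix::Diagonal(n, keep * diag_y)
  ## rhs assignments mirror the row-replacement order (later wins corners)
  rhs_p[b$outlet] <- 0
  rhs_p[b$bottom] <- 0
  rhs_p[b$top] <- psi_top
  rhs_p[b$inlet] <- psi_in

  A <- rbind(cbind(Aoo, Aop), cbind(Apo, App))
  sol <- solve_equilibrated(A, c(rhs_o, rhs_p))
  list(omega = sol[seq_len(n)], psi = sol[n + seq_len(n)])
}

## Velocities and contravariant transverse velocity from psi
velocities_from_psi <- function(ops, mesh, psi) {
  if (ops$axisym) {
    u <- ops$inv_y * as.numeric(ops$Dy %*% psi)
    v <- -ops$inv_y * as.numeric(ops$Dz %*% psi)
    ## axis limit via psi ~ (1/2) u0 r^2 + c r^4 through the first two
    ## off-axis nodes (the naive 2 psi / r^2 is only O(r^2) accurate)
    ax <- ops$bnd$bottom
    j2 <- node_index(1:ops$nz, 2L, ops$nz)
    j3 <- node_index(1:ops$nz, 3L, ops$nz)
    r2 <- ops$y[j2]; r3 <- ops$y[j3]
    u[ax] <- 2 * (psi[j2] * r3^4 - psi[j3] * r2^4) /
      (r2^2 * r3^4 - r3^2 * r2^4)
    v[ax] <- 0
  } else {
    u <- as.numeric(ops$Dy %*% psi)
    v <- -as.numeric(ops$Dz %*% psi)
  }
  u_eta <- -u * ops$g + v / ops$B
  list(u = u, v = v, u_eta = u_eta)
}

## Spatial right-hand-side operator of the vorticity transport equation
vorticity_rhs_operator <- function(ops, vel, nu) {
  D <- Matrix::Diagonal
  Adv <- D(x = pmax(vel$u, 0)) %*% ops$DXI_b + D(x = pmin(vel$u, 0)) %*% ops$DXI_f +
    D(x = pmax(vel$u_eta, 0)) %*% ops$DETA_b + D(x = pmin(vel$u_eta, 0)) %*% ops$DETA_f
  Op <- -Adv + nu * ops$Lom
  if (ops$axisym) Op <- Op + D(x = vel$v * ops$inv_y)
  Op
}

new_flow_solution <- function(mesh, props, type, waveform, times, psi, omega,
                              wss, times_all = times, cycle_index = NULL,
                              residuals = NULL, steps_per_cycle = NULL) {
  structure(list(mesh = mesh, props = props, type = type,
                 waveform = waveform, times = times,
                 psi = psi, omega = omega, wss = wss,
                 times_all = times_all, cycle_index = cycle_index,
                 residuals = residuals, steps_per_cycle = steps_per_cycle),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>", x$type, "on", x$mesh$mode, "mesh\n")
  cat(sprintf("  %d snapshot(s) retained; wall sides: %s\n",
              length(x$times), paste(names(x$wss), collapse = ", ")))
  if (!is.null(x$residuals))
    cat(sprintf("  steady residual %.3g after %d iterations\n",
                utils::tail(x$residuals, 1), length(x$residuals)))
  invisible(x)
}

wss_sign <- function(side) if (side == "bottom") -1 else 1

## Wall shear stress vectors (signed, streamwise-positive) from a vorticity
## field, per wall side
wss_from_omega <- function(ops, mesh, props, omega_v) {
  nz <- ops$nz; nr <- ops$nr
  out <- list(top = props$viscosity * omega_v[node_index(1:nz, nr, nz)])
  if (mesh$mode == "planar-2D")
    out$bottom <- -props$viscosity * omega_v[node_index(1:nz, 1L, nz)]
  out
}

#' Solve steady incompressible flow
#'
#' Pseudo-transient continuation of the stream-function / vorticity system
#' to steady state, with a fully developed (Poiseuille) inlet profile at
#' mean velocity `inflow`, no-slip rigid walls, and a zero-gradient outlet.
#'
#' @param mesh a [build_mesh()] mesh
#' @param props [fluid_properties()]
#' @param inflow mean inlet velocity (m/s), > 0 for forward flow
#' @param tol relative steady-state tolerance on the vorticity update; the
#'   default sits safely above the roundoff floor of the wall-vorticity
#'   closure (which differences nearly equal stream-function values over
#'   the squared near-wall spacing) while being far below the level that
#'   would move WSS noticeably
#' @param max_iter pseudo-time iteration budget
#' @param quiet suppress progress
#' @return a `flow_solution` with a single snapshot
#' @export
solve_steady <- function(mesh, props = fluid_properties(), inflow,
                         tol = 3e-5, max_iter = 60L, quiet = TRUE) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  if (inflow == 0) stop("inflow must be nonzero")
  ops <- flow_operators(mesh)
  thom <- wall_thom_geom(mesh)
  inlet <- inlet_profile_fun(mesh, props, inflow)(0)
  psi_in <- inlet$psi[, 1]; omega_in <- inlet$omega[, 1]
  psi_top <- psi_in[ops$nr]
  nu <- props$nu

  ## Picard iteration on the monolithic steady (omega, psi) system; the
  ## nonlinearity enters only through the frozen advection velocities
  psi <- rep(psi_in, each = ops$nz)
  omega_v <- rep(omega_in, each = ops$nz)
  hist <- numeric(0)
  relax <- 0.8
  for (it in seq_len(max_iter)) {
    vel <- velocities_from_psi(ops, mesh, psi)
    sol <- coupled_step(ops, mesh, thom, vel, nu, idt = 0, theta = 1,
                        omega_old = omega_v, psi_in = psi_in,
                        omega_in = omega_in, psi_top = psi_top)
    res <- max(abs(sol$omega - omega_v)) / max(max(abs(sol$omega)), 1e-12)
    hist <- c(hist, res)
    omega_v <- relax * sol$omega + (1 - relax) * omega_v
    psi <- relax * sol$psi + (1 - relax) * psi
    if (!quiet) message(sprintf("  steady Picard %3d res %.3e", it, res))
    if (res < tol) { omega_v <- sol$omega; psi <- sol$psi; break }
  }
  if (utils::tail(hist, 1) >= tol)
    solver_error(sprintf(
      "steady flow solve did not converge in %d iterations (last residual %.3e)",
      max_iter, utils::tail(hist, 1)), residuals = hist)
  wss <- lapply(wss_from_omega(ops, mesh, props, omega_v), function(v)
    matrix(v, ncol = 1))
  new_flow_solution(mesh, props, "steady", NULL, times = 0,
                    psi = matrix(psi, ncol = 1),
                    omega = matrix(omega_v, ncol = 1),
                    wss = wss, residuals = hist)
}

#' Solve pulsatile incompressible flow
#'
#' Time-steps the stream-function / vorticity system over `cycles` cardiac
#' cycles driven by a fitted inlet waveform, retaining the final cycle's
#' field snapshots (the convention for periodic hemodynamics) and the wall
#' shear stress series of every cycle for periodicity audits.
#'
#' The inlet profile is the fully developed pulsatile (Womersley /
#' oscillatory channel) profile of the waveform; walls are rigid no-slip;
#' the outlet is zero-gradient. Time integration is an implicit theta
#' scheme (Crank-Nicolson by default) with upwinded advection.
#'
#' @param mesh a [build_mesh()] mesh
#' @param props [fluid_properties()]
#' @param waveform a [fit_waveform()] object (mean inlet velocity over time)
#' @param cycles number of cycles (>= 1); analysis uses the final one
#' @param steps_per_cycle time steps per cycle
#' @param theta implicit weight (0.5 = Crank-Nicolson, 1 = backward Euler)
#' @param cfl_limit advective CFL guard; exceeded => solver error naming the
#'   offending step size
#' @param quiet suppress progress
#' @return a `flow_solution` with `steps_per_cycle + 1` final-cycle
#'   snapshots and all-cycle WSS series
#' @export
solve_pulsatile <- function(mesh, props = fluid_properties(), waveform,
                            cycles = 5L, steps_per_cycle = 200L,
                            theta = 0.5, cfl_limit = 15, quiet = TRUE) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(waveform, "waveform"))
  if (cycles < 1L) stop("cycles must be >= 1")
  ops <- flow_operators(mesh)
  thom <- wall_thom_geom(mesh)
  inlet_fun <- inlet_profile_fun(mesh, props, waveform)
  T <- waveform$period
  dt <- T / steps_per_cycle
  nu <- props$nu

  ## CFL guard (implicit scheme is stable, but accuracy degrades)
  vmax <- waveform_peak(waveform)
  dz <- mesh$z[2] - mesh$z[1]
  cfl <- vmax * dt / dz
  if (cfl > cfl_limit)
    solver_error(sprintf(
      "advective CFL %.1f exceeds limit %.1f at step size dt = %.4g s; increase steps_per_cycle",
      cfl, cfl_limit, dt))

  nt_all <- cycles * steps_per_cycle
  times_all <- dt * (0:nt_all)
  in0 <- inlet_fun(0)
  ## initialize from the developed profile replicated along the duct
  psi <- rep(in0$psi[, 1], each = ops$nz)
  omega_v <- rep(in0$omega[, 1], each = ops$nz)
  n_keep <- steps_per_cycle + 1L
  psi_keep <- matrix(NA_real_, ops$n, n_keep)
  omega_keep <- matrix(NA_real_, ops$n, n_keep)
  wss_all <- lapply(wss_from_omega(ops, mesh, props, omega_v), function(v)
    matrix(NA_real_, length(v), nt_all + 1L))
  for (s in names(wss_all)) wss_all[[s]][, 1] <- wss_from_omega(ops, mesh, props, omega_v)[[s]]
  keep_from <- nt_all - steps_per_cycle   # snapshot index (0-based) where final cycle starts
  if (keep_from == 0L) { psi_keep[, 1] <- psi; omega_keep[, 1] <- omega_v }

  for (step in seq_len(nt_all)) {
    t_new <- times_all[step + 1L]
    inn <- inlet_fun(t_new)
    psi_in <- inn$psi[, 1]; omega_in <- inn$omega[, 1]
    psi_top <- psi_in[ops$nr]
    vel <- velocities_from_psi(ops, mesh, psi)
    sol <- coupled_step(ops, mesh, thom, vel, nu, idt = 1 / dt, theta = theta,
                        omega_old = omega_v, psi_in = psi_in,
                        omega_in = omega_in, psi_top = psi_top)
    omega_v <- sol$omega; psi <- sol$psi
    w <- wss_from_omega(ops, mesh, props, omega_v)
    for (s in names(w)) wss_all[[s]][, step + 1L] <- w[[s]]
    if (step >= keep_from) {
      k <- step - keep_from + 1L
      psi_keep[, k] <- psi; omega_keep[, k] <- omega_v
    }
    if (!quiet && step %% steps_per_cycle == 0)
      message(sprintf("  cycle %d/%d complete", step %/% steps_per_cycle, cycles))
  }
  times_final <- times_all[(keep_from + 1L):(nt_all + 1L)]
  cycle_index <- pmin(cycles, 1L + (seq_along(times_all) - 2L) %/% steps_per_cycle)
  cycle_index[1] <- 1L
  new_flow_solution(mesh, props, "pulsatile", waveform,
                    times = times_final, psi = psi_keep, omega = omega_keep,
                    wss = wss_all, times_all = times_all,
                    cycle_index = cycle_index,
                    steps_per_cycle = as.integer(steps_per_cycle))
}

#' Extract the wall shear stress series
#'
#' Signed (streamwise-positive) tangential traction at every endothelial
#' interface point, per wall side, over the retained time axis.
#'
#' @param solution a `flow_solution`
#' @param final_cycle_only keep only the final cycle (the analysis
#'   convention); otherwise the full multi-cycle series
#' @return object of class `wss_series`: per side, arc-length positions `s`
#'   (m) and the tau matrix (positions x times, Pa)
#' @export
extract_wss <- function(solution, final_cycle_only = TRUE) {
  stopifnot(inherits(solution, "flow_solution"))
  if (length(solution$times) < 1L || is.null(solution$wss))
    stop("flow solution carries no snapshots / interface data")
  mesh <- solution$mesh
  times <- solution$times_all
  keep <- if (final_cycle_only && solution$type == "pulsatile") {
    nall <- length(times)
    (nall - solution$steps_per_cycle):nall
  } else seq_along(times)
  sides <- lapply(names(solution$wss), function(sd) {
    wall_side <- if (sd == "top") names(mesh$walls)[1] else "lower"
    list(side = sd,
         s = interface_arclength(mesh, if (mesh$mode == "axisymmetric-2D") "outer"
                                 else if (sd == "top") "upper" else "lower"),
         tau = solution$wss[[sd]][, keep, drop = FALSE])
  })
  names(sides) <- names(solution$wss)
  structure(list(sides = sides, times = times[keep],
                 period = if (!is.null(solution$waveform)) solution$waveform$period else NA_real_),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series> %d side(s), %d positions x %d times\n",
              length(x$sides), length(x$sides[[1]]$s), length(x$times)))
  invisible(x)
}

#' Volumetric flux through each cross-section
#'
#' In the stream-function formulation the flux is `2 pi (psi_wall -
#' psi_axis)` (axisymmetric) or `psi_upper - psi_lower` (planar, per unit
#' depth), so inlet and outlet flux agree to machine precision at every
#' snapshot: discrete mass conservation is exact by construction.
#'
#' @param solution a `flow_solution`
#' @param snapshot snapshot index (default: last)
#' @return numeric vector of fluxes per axial station (m^3/s or m^2/s)
#' @export
mass_flux <- function(solution, snapshot = ncol(solution$psi)) {
  mesh <- solution$mesh
  psi <- matrix(solution$psi[, snapshot], mesh$nz, mesh$nr)
  dpsi <- psi[, mesh$nr] - psi[, 1]
  if (mesh$mode == "axisymmetric-2D") 2 * pi * dpsi else dpsi
}

#' Velocity field of a snapshot
#'
#' @param solution a `flow_solution`
#' @param snapshot snapshot index into the retained (final-cycle) snapshots
#' @return list of `nz x nr` matrices `uz` (axial) and `uy`
#'   (radial/transverse), m/s
#' @export
flow_velocity <- function(solution, snapshot = ncol(solution$psi)) {
  mesh <- solution$mesh
  ops <- flow_operators(mesh)
  vel <- velocities_from_psi(ops, mesh, solution$psi[, snapshot])
  list(uz = matrix(vel$u, mesh$nz, mesh$nr),
       uy = matrix(vel$v, mesh$nz, mesh$nr))
}

#' Pressure field of a snapshot (diagnostic reconstruction)
#'
#' Recovers pressure from the velocity field through a pressure Poisson
#' equation with the convective sources, wall/axis zero-normal-gradient
#' rows, axial momentum rows at inlet and outlet, and a zero reference at
#' the outlet. For pulsatile solutions the local acceleration enters via a
#' backward difference of the stored snapshots.
#'
#' @param solution a `flow_solution`
#' @param snapshot snapshot index
#' @return `nz x nr` matrix of pressure (Pa), zero-referenced at the outlet
#' @export
flow_pressure <- function(solution, snapshot = ncol(solution$psi)) {
  mesh <- solution$mesh
  props <- solution$props
  ops <- flow_operators(mesh)
  vel <- velocities_from_psi(ops, mesh, solution$psi[, snapshot])
  u <- vel$u; v <- vel$v
  az <- u * as.numeric(ops$Dz %*% u) + v * as.numeric(ops$Dy %*% u)
  ar <- u * as.numeric(ops$Dz %*% v) + v * as.numeric(ops$Dy %*% v)
  div_a <- as.numeric(ops$Dz %*% az) + as.numeric(ops$Dy %*% ar)
  if (ops$axisym) div_a <- div_a + ops$inv_y * ar
  dudt <- rep(0, ops$n)
  if (solution$type == "pulsatile" && snapshot > 1) {
    dt <- solution$times[snapshot] - solution$times[snapshot - 1]
    velp <- velocities_from_psi(ops, mesh, solution$psi[, snapshot - 1])
    dudt <- (u - velp$u) / dt
  }
  rho <- props$density; mu <- props$viscosity
  lap_u <- as.numeric(ops$Lap %*% u)
  if (ops$axisym) lap_u <- lap_u    # z-component Laplacian is the scalar one
  M <- ops$Lap
  rhs <- -rho * div_a
  b <- ops$bnd
  M <- set_operator_rows(M, b$inlet, ops$Dz)
  M <- set_operator_rows(M, b$outlet, ops$Dz)
  rhs[b$inlet] <- (mu * lap_u - rho * (az + dudt))[b$inlet]
  rhs[b$outlet] <- (mu * lap_u - rho * (az + dudt))[b$outlet]
  M <- set_operator_rows(M, b$bottom, ops$Dy)
  M <- set_operator_rows(M, b$top, ops$Dy)
  rhs[c(b$bottom, b$top)] <- 0
  pin <- node_index(ops$nz, 2L, ops$nz)
  M <- set_identity_rows(M, pin)
  rhs[pin] <- 0
  p <- as.numeric(Matrix::solve(M, rhs))
  matrix(p - p[pin], mesh$nz, mesh$nr)
}
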