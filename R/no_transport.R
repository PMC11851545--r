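#' Transport parameters of the NO model
#'
#' Defaults are the model's published constants: lumen diffusivity
#' `Dl = 3.3e-9` m^2/s; pseudo-second-order oxidation rate
#' `koxgen = 7.56e-6` (interpreted as nM^-1 s^-1 so that the quadratic
#' sink `koxgen * cl^2` is dimensionally consistent; the term is in any
#' case negligible at nanomolar concentrations); red-blood-cell scavenging
#' `kery = 2.3` s^-1; wall diffusivity `Dw = 8.48e-10` m^2/s; first-order
#' wall consumption `kw = 0.01` s^-1; and the hyperbolic endothelial
#' production law constants `Rbasal = 2.13` nM/s, `Rmax = 457.5` nM/s,
#' `b = 3.5` Pa. `delta_en` is the endothelium thickness (m) used to
#' convert the volumetric production rate into an interface flux
#' `R_NO * delta_en`.
#'
#' @param Dl,koxgen,kery,Dw,kw,Rbasal,Rmax,b,delta_en see description
#' @return object of class `transport_params`
#' @export
transport_params <- function(Dl = 3.3e-9, koxgen = 7.56e-6, kery = 2.3,
                             Dw = 8.48e-10, kw = 0.01,
                             Rbasal = 2.13, Rmax = 457.5, b = 3.5,
                             delta_en = 2.5e-6) {
  p <- list(Dl = Dl, koxgen = koxgen, kery = kery, Dw = Dw, kw = kw,
            Rbasal = Rbasal, Rmax = Rmax, b = b, delta_en = delta_en)
  if (any(unlist(p[c("Dl", "koxgen", "kery", "Dw", "kw", "b", "delta_en")]) <= 0))
    stop("diffusivities, rate constants, b and delta_en must be strictly positive")
  if (Rbasal < 0 || Rmax < 0) stop("production rates must be non-negative")
  structure(p, class = "transport_params")
}

#' Endothelial NO production rate (hyperbolic shear response)
#'
#' \deqn{R_{NO} = R_{basal} + R_{max} |\tau_w| / (|\tau_w| + b)}
#' Monotone nondecreasing in the shear magnitude, saturating at
#' `Rbasal + Rmax`.
#'
#' @param tau_w wall shear stress (Pa); the absolute value is used
#' @param params [transport_params()]
#' @return production rate (nM/s)
#' @examples
#' production_rate(0)            # basal rate, 2.13 nM/s
#' production_rate(3.5)          # half-saturation: Rbasal + Rmax/2
#' @export
production_rate <- function(tau_w, params = transport_params()) {
  if (any(!is.finite(tau_w))) stop("tau_w must be finite")
  a <- abs(tau_w)
  params$Rbasal + params$Rmax * a / (a + params$b)
}

#' Lumen NO consumption rate
#'
#' Oxidation by oxygen (pseudo-second-order) plus scavenging by red blood
#' cells (first-order): `koxgen cl^2 + kery cl`, applied as a sink.
#'
#' @param cl lumen NO concentration (nM), non-negative
#' @param params [transport_params()]
#' @return consumption rate (nM/s)
#' @export
lumen_reaction <- function(cl, params = transport_params()) {
  if (any(cl < 0)) stop("negative lumen concentration")
  params$koxgen * cl^2 + params$kery * cl
}

## WSS keyed by mesh wall side names ("outer"/"upper" <- top, "lower" <- bottom)
tau_by_side <- function(mesh, wss_cols) {
  out <- list()
  for (sd in names(mesh$walls))
    out[[sd]] <- if (sd == "lower") wss_cols$bottom else wss_cols$top
  out
}

#' Solve the coupled lumen/wall NO transport problem
#'
#' Lumen: convection-diffusion with the oxidation + scavenging sink,
#' velocities taken from the flow solution's stream function (face fluxes
#' are exact stream-function differences, so advection conserves mass
#' discretely). Wall: diffusion with first-order consumption, no
#' convection. The endothelial production enters as an interface flux
#' `R_NO(|tau_w|) * delta_en` through dedicated interface-concentration
#' unknowns that enforce flux continuity; lumen and wall concentrations
#' meet these unknowns continuously. Inlet concentration is 0 nM
#' (upstream blood is an NO sink), the outlet is convective outflow, the
#' outer wall and any symmetry axis are zero-flux.
#'
#' For a pulsatile flow solution the final flow cycle is replayed
#' periodically for `cycles` cycles of implicit-Euler transport steps
#' starting from the steady field of the cycle-averaged flow, and the
#' final transport cycle is retained. For a steady flow solution the
#' steady transport problem is solved directly.
#'
#' @param mesh the mesh shared with the flow solution
#' @param flow a [solve_steady()] or [solve_pulsatile()] solution on `mesh`
#' @param params [transport_params()]
#' @param cycles transport cycles for the pulsatile case
#' @param fixed_interface optional named list (side -> nM) clamping the
#'   interface concentration instead of the production flux balance
#'   (validation aid)
#' @param quiet suppress progress
#' @return object of class `no_solution`: cell-centre lumen (`cl`) and wall
#'   (`cw`) concentration snapshots, interface concentrations (`cs`), the
#'   production-rate trace, times, and the finite-volume geometry
#' @export
solve_no <- function(mesh, flow, params = transport_params(), cycles = 5L,
                     fixed_interface = NULL, quiet = TRUE) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(flow, "flow_solution"))
  fm <- flow$mesh
  if (fm$nz != mesh$nz || fm$nr != mesh$nr || fm$mode != mesh$mode)
    stop("flow solution was computed on a different mesh")
  fvg <- fv_geometry(mesh)
  n <- fvg$n_unknown

  wss <- extract_wss(flow)
  prod_trace <- NULL

  if (flow$type == "steady") {
    tauS <- tau_by_side(mesh, lapply(wss$sides, function(s) s$tau[, 1]))
    names(tauS) <- names(mesh$walls)
    q_s <- lapply(tauS, function(tv)
      production_rate(face_tau(fvg, tv), params) * params$delta_en)
    cvec <- rep(0, n)
    for (pic in 1:3) {
      sys <- assemble_no_system(fvg, params, flow$psi[, 1], q_s, 0, cvec,
                                fixed_interface)
      cnew <- solve_equilibrated(sys$A, sys$b)
      if (max(abs(cnew - cvec)) < 1e-10 * max(abs(cnew), 1e-12)) { cvec <- cnew; break }
      cvec <- cnew
    }
    return(new_no_solution(fvg, params, times = 0,
                           C = matrix(cvec, ncol = 1), flow = flow,
                           q_s_trace = list(q_s),
                           psi_keep = flow$psi[, 1, drop = FALSE]))
  }

  ## pulsatile: replay the final flow cycle periodically
  spc <- flow$steps_per_cycle
  dt <- flow$waveform$period / spc
  nt <- spc + 1L
  wcols <- lapply(wss$sides, function(s) s$tau)      # nz x nt, final cycle

  ## initial condition: steady field of the cycle-averaged flow with the
  ## cycle-averaged production rate
  psi_mean <- rowMeans(flow$psi[, 1:spc, drop = FALSE])
  q_mean <- list()
  for (sd in names(mesh$walls)) {
    key <- if (sd == "lower") "bottom" else "top"
    tmat <- wcols[[key]]
    qk <- rowMeans(sapply(1:spc, function(k)
      production_rate(face_tau(fvg, tmat[, k]), params)))
    q_mean[[sd]] <- qk * params$delta_en
  }
  cvec <- rep(0, n)
  for (pic in 1:3) {
    sys <- assemble_no_system(fvg, params, psi_mean, q_mean, 0, cvec,
                              fixed_interface)
    cvec <- solve_equilibrated(sys$A, sys$b)
  }

  C_keep <- matrix(NA_real_, n, nt)
  psi_keep <- matrix(NA_real_, nrow(flow$psi), nt)
  q_keep <- vector("list", nt)
  total_steps <- cycles * spc
  for (step in seq_len(total_steps)) {
    k <- ((step - 1L) %% spc) + 2L     # snapshot index at t^{n+1} within cycle
    psi_k <- flow$psi[, k]
    q_s <- list()
    for (sd in names(mesh$walls)) {
      key <- if (sd == "lower") "bottom" else "top"
      q_s[[sd]] <- production_rate(face_tau(fvg, wcols[[key]][, k]), params) *
        params$delta_en
    }
    sys <- assemble_no_system(fvg, params, psi_k, q_s, 1 / dt, cvec,
                              fixed_interface)
    cvec <- solve_equilibrated(sys$A, sys$b)
    if (step > total_steps - spc) {
      idx <- step - (total_steps - spc) + 1L
      C_keep[, idx] <- cvec
      psi_keep[, idx] <- psi_k
      q_keep[[idx]] <- q_s
    }
    if (!quiet && step %% spc == 0)
      message(sprintf("  NO cycle %d/%d complete", step %/% spc, cycles))
  }
  C_keep[, 1] <- C_keep[, nt]   # periodic state: cycle start = cycle end
  psi_keep[, 1] <- psi_keep[, nt]
  q_keep[[1]] <- q_keep[[nt]]
  new_no_solution(fvg, params, times = dt * (0:spc), C = C_keep, flow = flow,
                  q_s_trace = q_keep, psi_keep = psi_keep)
}

new_no_solution <- function(fvg, params, times, C, flow, q_s_trace, psi_keep) {
  Nl <- fvg$Nl
  cl <- C[seq_len(Nl), , drop = FALSE]
  cw <- list(); cs <- list()
  for (sd in fvg$sides) {
    ow <- fvg$off_wall[[sd]]; oi <- fvg$off_iface[[sd]]
    Nw <- length(fvg$walls[[sd]]$V)
    cw[[sd]] <- C[ow + seq_len(Nw), , drop = FALSE]
    cs[[sd]] <- C[oi + seq_len(fvg$nci), , drop = FALSE]
  }
  structure(list(fvg = fvg, params = params, times = times,
                 cl = cl, cw = cw, cs = cs,
                 q_s_trace = q_s_trace, psi = psi_keep,
                 flow_type = flow$type, period = if (!is.null(flow$waveform))
                   flow$waveform$period else NA_real_),
            class = "no_solution")
}

#' @export
print.no_solution <- function(x, ...) {
  cat("<no_solution>", x$flow_type, "driving flow,",
      length(x$times), "snapshot(s)\n")
  cat(sprintf("  lumen c range [%.3g, %.3g] nM; interface mean %.3g nM\n",
              min(x$cl), max(x$cl), mean(x$cs[[1]][, ncol(x$cs[[1]])])))
  invisible(x)
}

#' Discrete NO source/sink balance audit
#'
#' For a steady solution (or any single snapshot of a periodic one at
#' steady cycling), totals the endothelial production and compares it with
#' lumen consumption + wall consumption + net advective/diffusive outflow.
#' The finite-volume scheme telescopes exactly, so the relative imbalance
#' reflects only the quadratic-sink linearization lag and solver roundoff.
#'
#' @param no_sol a [solve_no()] solution
#' @param snapshot column index (default: last)
#' @return list with the individual terms (nM m^3/s) and the relative
#'   imbalance
#' @export
no_balance <- function(no_sol, snapshot = ncol(no_sol$cl)) {
  fvg <- no_sol$fvg; params <- no_sol$params
  cl <- no_sol$cl[, snapshot]
  psi <- no_sol$psi[, snapshot]
  production <- 0; wall_cons <- 0
  for (sd in fvg$sides) {
    q <- no_sol$q_s_trace[[min(snapshot, length(no_sol$q_s_trace))]][[sd]]
    production <- production + sum(q * fvg$walls[[sd]]$iface$area)
    wall_cons <- wall_cons + sum(fvg$walls[[sd]]$V * params$kw *
                                   no_sol$cw[[sd]][, snapshot])
  }
  lumen_cons <- sum(fvg$Vl * lumen_reaction(pmax(cl, 0), params))
  ## boundary advective + diffusive losses, recomputed from the stream
  ## function exactly as the assembly does
  Fin <- fvg$fac * (psi[fvg$f_in$psi_b] - psi[fvg$f_in$psi_a])
  inlet_loss <- sum((params$Dl * fvg$f_in$dcoef + pmax(-Fin, 0)) *
                      cl[fvg$f_in$P])
  Fout <- fvg$fac * (psi[fvg$f_out$psi_b] - psi[fvg$f_out$psi_a])
  outlet_loss <- sum(pmax(Fout, 0) * cl[fvg$f_out$P])
  bal <- production - lumen_cons - wall_cons - inlet_loss - outlet_loss
  list(production = production, lumen_consumption = lumen_cons,
       wall_consumption = wall_cons,
       inlet_loss = inlet_loss, outlet_loss = outlet_loss,
       relative_imbalance = abs(bal) / production)
}

#' Grid-independence study on the NO field
#'
#' Repeatedly refines the mesh by `factor` (10% per step by default),
#' solving steady flow and steady NO transport each time, until the
#' volume-averaged lumen NO concentration changes by less than `threshold`
#' (5% by default) between consecutive meshes.
#'
#' @param geom a [vessel_geometry()]
#' @param inflow steady mean inlet velocity (m/s)
#' @param props [fluid_properties()]
#' @param params [transport_params()]
#' @param mode mesh mode
#' @param resolution starting resolution (see [build_mesh()])
#' @param factor per-step refinement factor
#' @param threshold relative-change acceptance threshold; 0 is degenerate
#'   (never accepts) and simply exhausts the budget with a failure flag
#' @param max_refinements refinement budget
#' @param quiet suppress progress
#' @return object of class `mesh_independence_report`: the convergence
#'   trace, acceptance flag, and accepted resolution
#' @export
mesh_independence_study <- function(geom, inflow = 0.2,
                                    props = fluid_properties(),
                                    params = transport_params(),
                                    mode = "axisymmetric-2D",
                                    resolution = list(nz = 25L, nr = 13L, nw = 6L),
                                    factor = 1.1, threshold = 0.05,
                                    max_refinements = 8L, quiet = TRUE) {
  if (factor <= 1) stop("refinement factor must be > 1")
  mesh <- build_mesh(geom, resolution, mode = mode)
  trace <- data.frame(step = integer(), nz = integer(), nr = integer(),
                      nw = integer(), avg_no_nM = numeric(),
                      delta = numeric())
  avg_prev <- NA_real_
  converged <- FALSE
  for (step in 0:max_refinements) {
    fl <- solve_steady(mesh, props, inflow)
    no <- solve_no(mesh, fl, params)
    avg <- stats::weighted.mean(no$cl[, 1], no$fvg$Vl)
    delta <- if (is.na(avg_prev)) NA_real_ else abs(avg - avg_prev) / abs(avg_prev)
    trace <- rbind(trace, data.frame(step = step, nz = mesh$nz, nr = mesh$nr,
                                     nw = mesh$nw, avg_no_nM = avg,
                                     delta = delta))
    if (!quiet) message(sprintf("  refinement %d: %dx%d avg %.4g nM delta %s",
                                step, mesh$nz, mesh$nr, avg,
                                ifelse(is.na(delta), "-", sprintf("%.3f", delta))))
    if (!is.na(delta) && delta < threshold) { converged <- TRUE; break }
    if (step < max_refinements) mesh <- refine(mesh, factor)
    avg_prev <- avg
  }
  structure(list(trace = trace, converged = converged,
                 threshold = threshold, factor = factor,
                 accepted = if (converged)
                   trace[nrow(trace), c("nz", "nr", "nw")] else NULL),
            class = "mesh_independence_report")
}

#' @export
print.mesh_independence_report <- function(x, ...) {
  cat("<mesh_independence_report>",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(threshold %.3g, factor %.2f)\n", x$threshold, x$factor))
  print(x$trace, row.names = FALSE)
  invisible(x)
}
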