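## Cell-centred finite-volume machinery for the NO transport equations on
## the mapped structured grid. Advective face fluxes are taken exactly from
## stream-function differences at the face endpoints (flux through a curve
## a->b equals 2*pi*(psi_b - psi_a) for the Stokes stream function, or
## psi_b - psi_a per unit depth in planar mode), so discrete mass
## conservation is inherited from the flow solver. First-order upwinding
## plus implicit Euler gives an M-matrix and therefore clip-free
## non-negative concentrations.

## Precompute the finite-volume geometry and index maps for a mesh.
## Unknown ordering: lumen cells (column-major, axial fastest), then wall
## cells per side, then interface-face unknowns per side.
fv_geometry <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr; nw <- mesh$nw
  axi <- mesh$mode == "axisymmetric-2D"
  fac <- if (axi) 2 * pi else 1
  nci <- nz - 1L            # cells per axial row / faces per interface
  ncj <- nr - 1L
  Nl <- nci * ncj
  sides <- names(mesh$walls)
  Nw_side <- nci * (nw - 1L)
  n_side <- length(sides)
  off_wall <- Nl + (seq_len(n_side) - 1L) * Nw_side
  names(off_wall) <- sides
  off_iface <- Nl + n_side * Nw_side + (seq_len(n_side) - 1L) * nci
  names(off_iface) <- sides
  n_unknown <- Nl + n_side * Nw_side + n_side * nci

  node_id <- function(i, j) (j - 1L) * nz + i
  lum_cell <- function(i, j) (j - 1L) * nci + i

  cell_center <- function(Zb, Yb) {
    ni <- nrow(Zb) - 1L; nj <- ncol(Zb) - 1L
    i <- seq_len(ni); j <- seq_len(nj)
    cz <- (Zb[i, j, drop = FALSE] + Zb[i + 1, j, drop = FALSE] +
           Zb[i + 1, j + 1, drop = FALSE] + Zb[i, j + 1, drop = FALSE]) / 4
    cy <- (Yb[i, j, drop = FALSE] + Yb[i + 1, j, drop = FALSE] +
           Yb[i + 1, j + 1, drop = FALSE] + Yb[i, j + 1, drop = FALSE]) / 4
    list(z = cz, y = cy)
  }
  face_geom <- function(za, ya, zb, yb) {
    len <- sqrt((zb - za)^2 + (yb - ya)^2)
    area <- len * (if (axi) 2 * pi * (ya + yb) / 2 else 1)
    list(area = area, mz = (za + zb) / 2, my = (ya + yb) / 2)
  }

  Z <- mesh$Z; Y <- mesh$Y
  lc <- cell_center(Z, Y)
  Vl <- as.vector(block_cell_volumes(Z, Y, mesh$mode))

  ## --- lumen axial internal faces: P=(i,j), N=(i+1,j), i=1..nci-1
  ia <- rep(seq_len(nci - 1L), ncj); ja <- rep(seq_len(ncj), each = nci - 1L)
  n1 <- node_id(ia + 1L, ja); n2 <- node_id(ia + 1L, ja + 1L)
  fg <- face_geom(Z[n1], Y[n1], Z[n2], Y[n2])
  dPN <- sqrt((lc$z[cbind(ia + 1L, ja)] - lc$z[cbind(ia, ja)])^2 +
              (lc$y[cbind(ia + 1L, ja)] - lc$y[cbind(ia, ja)])^2)
  fz <- list(P = lum_cell(ia, ja), N = lum_cell(ia + 1L, ja),
             psi_a = n1, psi_b = n2, dcoef = fg$area / dPN)

  ## --- lumen transverse internal faces: P=(i,j), N=(i,j+1), j=1..ncj-1
  it <- rep(seq_len(nci), ncj - 1L); jt <- rep(seq_len(ncj - 1L), each = nci)
  m1 <- node_id(it + 1L, jt + 1L); m2 <- node_id(it, jt + 1L)  # a -> b for +eta flux
  fgt <- face_geom(Z[m1], Y[m1], Z[m2], Y[m2])
  dPNt <- sqrt((lc$z[cbind(it, jt + 1L)] - lc$z[cbind(it, jt)])^2 +
               (lc$y[cbind(it, jt + 1L)] - lc$y[cbind(it, jt)])^2)
  ft <- list(P = lum_cell(it, jt), N = lum_cell(it, jt + 1L),
             psi_a = m1, psi_b = m2, dcoef = fgt$area / dPNt)

  ## --- inlet faces (cells (1, j)): inward +z flux from psi difference
  jb <- seq_len(ncj)
  a_in <- node_id(1L, jb); b_in <- node_id(1L, jb + 1L)
  fgi <- face_geom(Z[a_in], Y[a_in], Z[b_in], Y[b_in])
  d_in <- sqrt((lc$z[cbind(1L, jb)] - fgi$mz)^2 + (lc$y[cbind(1L, jb)] - fgi$my)^2)
  f_in <- list(P = lum_cell(1L, jb), psi_a = a_in, psi_b = b_in,
               dcoef = fgi$area / d_in)

  ## --- outlet faces (cells (nci, j)): outward +z flux
  a_out <- node_id(nz, jb); b_out <- node_id(nz, jb + 1L)
  f_out <- list(P = lum_cell(nci, jb), psi_a = a_out, psi_b = b_out)

  ## --- wall bands and interface faces per side
  walls <- list()
  for (sd in sides) {
    wb <- mesh$walls[[sd]]
    wc <- cell_center(wb$Z, wb$Y)
    Vw <- as.vector(block_cell_volumes(wb$Z, wb$Y, mesh$mode))
    if (any(Vw < 0)) { Vw <- -Vw }   # orientation of lower band
    wall_cell <- function(i, k) (k - 1L) * nci + i
    ## wall axial faces
    iw <- rep(seq_len(nci - 1L), nw - 1L); kw_ <- rep(seq_len(nw - 1L), each = nci - 1L)
    wn1 <- node_id_w(iw + 1L, kw_, nz); wn2 <- node_id_w(iw + 1L, kw_ + 1L, nz)
    fgw <- face_geom(wb$Z[wn1], wb$Y[wn1], wb$Z[wn2], wb$Y[wn2])
    dw <- sqrt((wc$z[cbind(iw + 1L, kw_)] - wc$z[cbind(iw, kw_)])^2 +
               (wc$y[cbind(iw + 1L, kw_)] - wc$y[cbind(iw, kw_)])^2)
    w_fz <- list(P = wall_cell(iw, kw_), N = wall_cell(iw + 1L, kw_),
                 dcoef = fgw$area / dw)
    ## wall transverse faces
    iwt <- rep(seq_len(nci), nw - 2L); kwt <- rep(seq_len(nw - 2L), each = nci)
    wm1 <- node_id_w(iwt, kwt + 1L, nz); wm2 <- node_id_w(iwt + 1L, kwt + 1L, nz)
    fgwt <- face_geom(wb$Z[wm1], wb$Y[wm1], wb$Z[wm2], wb$Y[wm2])
    dwt <- sqrt((wc$z[cbind(iwt, kwt + 1L)] - wc$z[cbind(iwt, kwt)])^2 +
                (wc$y[cbind(iwt, kwt + 1L)] - wc$y[cbind(iwt, kwt)])^2)
    w_ft <- list(P = wall_cell(iwt, kwt), N = wall_cell(iwt, kwt + 1L),
                 dcoef = fgwt$area / dwt)
    ## interface faces: between lumen boundary cells, the interface
    ## unknown, and the first wall cell row
    ii <- seq_len(nci)
    jlum <- if (sd == "lower") 1L else ncj
    jnode <- if (sd == "lower") 1L else nr
    inA <- node_id(ii, jnode); inB <- node_id(ii + 1L, jnode)
    fgI <- face_geom(Z[inA], Y[inA], Z[inB], Y[inB])
    dL <- sqrt((lc$z[cbind(ii, jlum)] - fgI$mz)^2 + (lc$y[cbind(ii, jlum)] - fgI$my)^2)
    dW <- sqrt((wc$z[cbind(ii, 1L)] - fgI$mz)^2 + (wc$y[cbind(ii, 1L)] - fgI$my)^2)
    walls[[sd]] <- list(V = Vw, center = wc,
                        fz = w_fz, ft = w_ft,
                        iface = list(lumP = lum_cell(ii, jlum),
                                     area = fgI$area, dL = dL, dW = dW,
                                     mz = fgI$mz, my = fgI$my))
  }

  list(mesh = mesh, fac = fac, axi = axi,
       nci = nci, ncj = ncj, Nl = Nl, nw = nw,
       sides = sides, off_wall = off_wall, off_iface = off_iface,
       n_unknown = n_unknown,
       Vl = Vl, lumen_center = lc,
       fz = fz, ft = ft, f_in = f_in, f_out = f_out,
       walls = walls)
}

node_id_w <- function(i, k, nz) (k - 1L) * nz + i

## Average nodal interface WSS magnitudes onto interface faces
face_tau <- function(fvg, tau_nodes) {
  i <- seq_len(fvg$nci)
  0.5 * (abs(tau_nodes[i]) + abs(tau_nodes[i + 1L]))
}

## Assemble the transport system A c = b for one implicit step.
## psi: node stream function (length nz*nr); q_s: list side -> endothelial
## production flux per interface face (nM m/s, i.e. R_NO * delta_en);
## idt = 1/dt (0 for steady); c_old: previous concentrations (also the
## linearization state for the quadratic sink); fixed_interface: optional
## named list side -> value, replacing the interface flux-balance rows by
## Dirichlet rows (used by slab oracles).
assemble_no_system <- function(fvg, params, psi, q_s, idt, c_old,
                               fixed_interface = NULL) {
  n <- fvg$n_unknown
  Dl <- params$Dl; Dw <- params$Dw
  I <- integer(0); J <- integer(0); X <- numeric(0)
  b <- numeric(n)
  add <- function(i, j, x) {
    I <<- c(I, i); J <<- c(J, j); X <<- c(X, rep_len(x, length(i)))
  }

  ## lumen internal faces: diffusion + upwind advection
  for (f in list(fvg$fz, fvg$ft)) {
    F <- fvg$fac * (psi[f$psi_b] - psi[f$psi_a])
    Fp <- pmax(F, 0); Fm <- pmin(F, 0)
    Dc <- Dl * f$dcoef
    add(f$P, f$P,  Dc + Fp); add(f$P, f$N, -Dc + Fm)
    add(f$N, f$N,  Dc - Fm); add(f$N, f$P, -Dc - Fp)
  }
  ## inlet: exterior concentration 0 (upstream blood is NO-depleted);
  ## diffusive exchange with the boundary value plus any outflow advection
  Fin <- fvg$fac * (psi[fvg$f_in$psi_b] - psi[fvg$f_in$psi_a])  # inward +z
  add(fvg$f_in$P, fvg$f_in$P, Dl * fvg$f_in$dcoef + pmax(-Fin, 0))
  ## outlet: pure convective outflow (inflow during reversal carries 0)
  Fout <- fvg$fac * (psi[fvg$f_out$psi_b] - psi[fvg$f_out$psi_a])
  add(fvg$f_out$P, fvg$f_out$P, pmax(Fout, 0))

  ## storage + lumen reaction (quadratic term Picard-linearized)
  cl_old <- c_old[seq_len(fvg$Nl)]
  add(seq_len(fvg$Nl), seq_len(fvg$Nl),
      fvg$Vl * (idt + params$kery + params$koxgen * pmax(cl_old, 0)))
  b[seq_len(fvg$Nl)] <- fvg$Vl * idt * cl_old

  for (sd in fvg$sides) {
    w <- fvg$walls[[sd]]
    ow <- fvg$off_wall[[sd]]; oi <- fvg$off_iface[[sd]]
    Nw <- length(w$V)
    for (f in list(w$fz, w$ft)) {
      if (length(f$P) == 0) next
      Dc <- Dw * f$dcoef
      add(ow + f$P, ow + f$P,  Dc); add(ow + f$P, ow + f$N, -Dc)
      add(ow + f$N, ow + f$N,  Dc); add(ow + f$N, ow + f$P, -Dc)
    }
    add(ow + seq_len(Nw), ow + seq_len(Nw), w$V * (idt + params$kw))
    b[ow + seq_len(Nw)] <- w$V * idt * c_old[ow + seq_len(Nw)]

    ## interface faces: lumen cell -- interface unknown -- first wall cell
    ifc <- w$iface
    nci <- fvg$nci
    DLc <- Dl * ifc$area / ifc$dL
    DWc <- Dw * ifc$area / ifc$dW
    sidx <- oi + seq_len(nci)
    widx <- ow + seq_len(nci)          # wall cells (i, k=1)
    add(ifc$lumP, ifc$lumP,  DLc); add(ifc$lumP, sidx, -DLc)
    add(widx, widx,  DWc);          add(widx, sidx, -DWc)
    if (!is.null(fixed_interface) && !is.null(fixed_interface[[sd]])) {
      add(sidx, sidx, 1)
      b[sidx] <- fixed_interface[[sd]]
    } else {
      add(sidx, sidx,  DLc + DWc)
      add(sidx, ifc$lumP, -DLc)
      add(sidx, widx, -DWc)
      b[sidx] <- q_s[[sd]] * ifc$area
    }
  }
  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n))
  list(A = A, b = b)
}
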