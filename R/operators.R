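## Sparse finite-difference operators on the mapped structured lumen grid.
##
## Logical coordinates: xi = z (axial, uniform, index i = 1..nz) and
## eta in [0,1] (transverse fraction, graded, index j = 1..nr), with the
## physical mapping y = A(xi) + eta * B(xi). Nodes are vectorized
## column-major with the axial index fastest: k = i + (j-1)*nz.
##
## Chain rule (g = (A' + eta B')/B):
##   f_z  = f_xi - g f_eta
##   f_y  = f_eta / B
##   f_zz = f_xixi - 2 g f_xieta + g^2 f_etaeta + (g g_eta - g_xi) f_eta
##   f_yy = f_etaeta / B^2
## with g_eta = B'/B and g_xi = (A'' + eta B'')/B - (A' + eta B') B'/B^2.

## 3-point first derivative on a nonuniform 1D grid (second order interior,
## one-sided second order at the ends)
d1_matrix <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  h1 <- x[i] - x[i - 1]; h2 <- x[i + 1] - x[i]
  rows <- c(i, i, i)
  cols <- c(i - 1, i, i + 1)
  vals <- c(-h2 / (h1 * (h1 + h2)),
            (h2 - h1) / (h1 * h2),
            h1 / (h2 * (h1 + h2)))
  ## one-sided second-order ends
  hA1 <- x[2] - x[1]; hA2 <- x[3] - x[2]
  rows <- c(rows, 1, 1, 1)
  cols <- c(cols, 1, 2, 3)
  vals <- c(vals,
            -(2 * hA1 + hA2) / (hA1 * (hA1 + hA2)),
            (hA1 + hA2) / (hA1 * hA2),
            -hA1 / (hA2 * (hA1 + hA2)))
  hB1 <- x[n] - x[n - 1]; hB2 <- x[n - 1] - x[n - 2]
  rows <- c(rows, n, n, n)
  cols <- c(cols, n, n - 1, n - 2)
  vals <- c(vals,
            (2 * hB1 + hB2) / (hB1 * (hB1 + hB2)),
            -(hB1 + hB2) / (hB1 * hB2),
            hB1 / (hB2 * (hB1 + hB2)))
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

## 3-point second derivative on a nonuniform 1D grid; end rows use the
## adjacent interior stencil (they are overwritten by boundary rows anyway)
d2_matrix <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  h1 <- x[i] - x[i - 1]; h2 <- x[i + 1] - x[i]
  rows <- c(i, i, i)
  cols <- c(i - 1, i, i + 1)
  vals <- c(2 / (h1 * (h1 + h2)),
            -2 / (h1 * h2),
            2 / (h2 * (h1 + h2)))
  ## ends: first-order one-sided second derivative
  rows <- c(rows, 1, 1, 1, n, n, n)
  cols <- c(cols, 1, 2, 3, n, n - 1, n - 2)
  hA1 <- x[2] - x[1]; hA2 <- x[3] - x[2]
  hB1 <- x[n] - x[n - 1]; hB2 <- x[n - 1] - x[n - 2]
  vals <- c(vals,
            2 / (hA1 * (hA1 + hA2)), -2 / (hA1 * hA2), 2 / (hA2 * (hA1 + hA2)),
            2 / (hB1 * (hB1 + hB2)), -2 / (hB1 * hB2), 2 / (hB2 * (hB1 + hB2)))
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

## One-sided first derivatives for upwinding (first order). direction
## "backward": (f_i - f_{i-1})/h; node 1 falls back to forward.
d1_upwind_matrix <- function(x, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  n <- length(x)
  if (direction == "backward") {
    i <- 2:n; h <- x[i] - x[i - 1]
    rows <- c(i, i, 1, 1); cols <- c(i, i - 1, 1, 2)
    vals <- c(1 / h, -1 / h, -1 / (x[2] - x[1]), 1 / (x[2] - x[1]))
  } else {
    i <- 1:(n - 1); h <- x[i + 1] - x[i]
    rows <- c(i, i, n, n); cols <- c(i, i + 1, n, n - 1)
    vals <- c(-1 / h, 1 / h, 1 / (x[n] - x[n - 1]), -1 / (x[n] - x[n - 1]))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

node_index <- function(i, j, nz) (j - 1L) * nz + i

## Boundary node index sets for the vectorized lumen grid
boundary_indices <- function(nz, nr) {
  list(inlet  = node_index(1L, 1:nr, nz),
       outlet = node_index(nz, 1:nr, nz),
       bottom = node_index(1:nz, 1L, nz),    # axis (axisym) / lower wall
       top    = node_index(1:nz, nr, nz))    # wall / upper wall
}

## Precompute all mapped-space operators and metric vectors for a mesh
flow_operators <- function(mesh) {
  nz <- mesh$nz; nr <- mesh$nr; n <- nz * nr
  axi <- mesh$mode == "axisymmetric-2D"
  Iz <- Matrix::Diagonal(nz); Ir <- Matrix::Diagonal(nr)
  Dxi_1   <- d1_matrix(mesh$z)
  Dxixi_1 <- d2_matrix(mesh$z)
  ## transverse derivatives through the smooth stretching map eta(sigma):
  ## d/deta = (1/eta') d/dsigma ;
  ## d2/deta2 = (1/eta'^2) d2/dsigma2 - (eta''/eta'^3) d/dsigma
  em <- mesh$eta_map
  Dsig  <- d1_matrix(em$sigma)
  Dsig2 <- d2_matrix(em$sigma)
  D1d <- Matrix::Diagonal
  De_1  <- D1d(x = 1 / em$dx) %*% Dsig
  Dee_1 <- D1d(x = 1 / em$dx^2) %*% Dsig2 - D1d(x = em$d2x / em$dx^3) %*% Dsig
  DXI   <- Matrix::kronecker(Ir, Dxi_1)
  DXIXI <- Matrix::kronecker(Ir, Dxixi_1)
  DETA   <- Matrix::kronecker(De_1, Iz)
  DETAETA <- Matrix::kronecker(Dee_1, Iz)
  DXIETA <- Matrix::kronecker(De_1, Dxi_1)
  DXI_b <- Matrix::kronecker(Ir, d1_upwind_matrix(mesh$z, "backward"))
  DXI_f <- Matrix::kronecker(Ir, d1_upwind_matrix(mesh$z, "forward"))
  DETA_b <- Matrix::kronecker(d1_upwind_matrix(mesh$eta, "backward"), Iz)
  DETA_f <- Matrix::kronecker(d1_upwind_matrix(mesh$eta, "forward"), Iz)

  eta_n <- rep(mesh$eta, each = nz)
  A1 <- rep(mesh$A1, nr); A2 <- rep(mesh$A2, nr)
  B  <- rep(mesh$B, nr);  B1 <- rep(mesh$B1, nr); B2 <- rep(mesh$B2, nr)
  g     <- (A1 + eta_n * B1) / B
  g_eta <- B1 / B
  g_xi  <- (A2 + eta_n * B2) / B - (A1 + eta_n * B1) * B1 / B^2
  y <- as.vector(mesh$Y)

  D <- Matrix::Diagonal
  Dz <- DXI - D(x = g) %*% DETA
  Dy <- D(x = 1 / B) %*% DETA
  Dzz <- DXIXI - 2 * (D(x = g) %*% DXIETA) + D(x = g^2) %*% DETAETA +
    D(x = g * g_eta - g_xi) %*% DETA
  Dyy <- D(x = 1 / B^2) %*% DETAETA

  inv_y <- if (axi) ifelse(abs(y) < 1e-14, 0, 1 / y) else rep(0, n)
  Lap <- Dzz + Dyy
  if (axi) Lap <- Lap + D(x = inv_y) %*% Dy
  if (axi) {
    ## Near the axis both psi_rr - psi_r/r (Stokes stream function, even
    ## expansion a r^2 + b r^4) and omega_rr + omega_r/r - omega/r^2 (odd
    ## expansion a r + b r^3) cancel to 8 b r^2 resp. 8 b r; the generic
    ## stencils lose that cancellation when divided by small r. Replace the
    ## radial part of the first off-axis row with the exact expansion form.
    j2 <- node_index(1:nz, 2L, nz); j3 <- node_index(1:nz, 3L, nz)
    r2 <- y[j2]; r3 <- y[j3]
    Rad_psi <- Dyy - D(x = inv_y) %*% Dy
    Rad_om  <- Dyy + D(x = inv_y) %*% Dy - D(x = inv_y^2)
    S_psi <- Matrix::sparseMatrix(
      i = c(j2, j2), j = c(j2, j3),
      x = c(8 / (r2^2 - r3^2), -8 * r2^2 / (r3^2 * (r2^2 - r3^2))),
      dims = c(n, n))
    S_om <- Matrix::sparseMatrix(
      i = c(j2, j2), j = c(j2, j3),
      x = c(8 / (r2^2 - r3^2), -8 * r2 / (r3 * (r2^2 - r3^2))),
      dims = c(n, n))
    Rad_psi <- set_operator_rows(Rad_psi, j2, S_psi)
    Rad_om  <- set_operator_rows(Rad_om, j2, S_om)
    E2  <- Dzz + Rad_psi
    Lom <- Dzz + Rad_om
  } else {
    E2  <- Dzz + Dyy
    Lom <- E2
  }

  list(nz = nz, nr = nr, n = n, axisym = axi,
       DXI = DXI, DETA = DETA,
       DXI_b = DXI_b, DXI_f = DXI_f, DETA_b = DETA_b, DETA_f = DETA_f,
       Dz = Dz, Dy = Dy, Dzz = Dzz, Dyy = Dyy, Lap = Lap, E2 = E2, Lom = Lom,
       g = g, B = B, y = y, inv_y = inv_y, eta_n = eta_n,
       bnd = boundary_indices(nz, nr))
}

## Replace rows of a sparse matrix with identity rows (Dirichlet) or with
## the rows of another operator (e.g. zero-gradient). `rows` is an index
## vector.
set_identity_rows <- function(M, rows) {
  n <- nrow(M)
  P <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% rows)))
  E <- Matrix::sparseMatrix(i = rows, j = rows, x = rep(1, length(rows)),
                            dims = c(n, n))
  P %*% M + E
}

## Solve A x = b after row and column equilibration (infinity norm).
## FD systems mix row scales over many orders of magnitude (1/h^2 terms,
## Thom closures, stream-function magnitudes), which otherwise trips the
## sparse solver's conditioning check.
solve_equilibrated <- function(A, b) {
  rsc <- Matrix::rowSums(abs(A))
  rsc[rsc == 0] <- 1
  Dr <- Matrix::Diagonal(x = 1 / rsc)
  A1 <- Dr %*% A
  csc <- Matrix::colSums(abs(A1))
  csc[csc == 0] <- 1
  Dc <- Matrix::Diagonal(x = 1 / csc)
  x <- Matrix::solve(A1 %*% Dc, as.numeric(Dr %*% b))
  as.numeric(Dc %*% x)
}

set_operator_rows <- function(M, rows, Op) {
  n <- nrow(M)
  keep <- as.numeric(!(seq_len(n) %in% rows))
  sel  <- 1 - keep
  Matrix::Diagonal(n, keep) %*% M + Matrix::Diagonal(n, sel) %*% Op
}
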