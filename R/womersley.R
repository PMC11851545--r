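## Closed-form pulsatile profiles: Womersley flow in a rigid circular tube
## and its planar-channel analogue. Used both as inlet boundary conditions
## (the profiles of fully developed pulsatile flow for a given flow-rate
## waveform) and as independent oracles for the time-stepping solver.

## Complex Bessel functions of the first kind, orders 0 and 1, by power
## series. Adequate to |z| ~ 25 in double precision, i.e. Womersley
## numbers through the physiological range.
besselJ0_complex <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z / 2)^2
  for (m in 1:60) {
    term <- term * q / (m * m)
    out <- out + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(out), 1))) break
  }
  out
}

besselJ1_complex <- function(z) {
  out <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  q <- -(z / 2)^2
  for (m in 1:60) {
    term <- term * q / (m * (m + 1))
    out <- out + term
    if (all(Mod(term) < 1e-17 * pmax(Mod(out), 1))) break
  }
  (z / 2) * out
}

#' Womersley number
#' @param R tube radius (m)
#' @param omega angular frequency (rad/s)
#' @param nu kinematic viscosity (m^2/s)
#' @export
womersley_number <- function(R, omega, nu) R * sqrt(omega / nu)

## Complex harmonic shape functions for a tube of radius R at radial
## fractions eta (0 = axis, 1 = wall), for angular frequency omega.
## Normalized so the cross-section-average of u is 1. Returns profiles of
## u, the Stokes stream function psi (u_z = psi_r / r), and azimuthal
## vorticity omega_v = -du/dr.
womersley_tube_shapes <- function(eta, R, omega, nu) {
  alpha <- womersley_number(R, omega, nu)
  Lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha  # i^{3/2} alpha
  J0L <- besselJ0_complex(Lam)
  J1L <- besselJ1_complex(Lam)
  den <- 1 - 2 * J1L / (Lam * J0L)
  u <- (1 - besselJ0_complex(Lam * eta) / J0L) / den
  psi <- R^2 * (eta^2 / 2 - eta * besselJ1_complex(Lam * eta) / (Lam * J0L)) / den
  om <- -(1 / R) * Lam * besselJ1_complex(Lam * eta) / (J0L * den)
  list(u = u, psi = psi, omega = om)
}

## Planar-channel analogue on centred coordinate s in [-H, H], normalized
## to unit mean velocity. psi is the planar stream function with
## psi(-H) = 0; u = dpsi/dy; omega_v = -du/dy.
channel_shapes <- function(s, H, omega, nu) {
  beta <- sqrt(complex(real = 0, imaginary = omega / nu))
  ch <- cosh(beta * H)
  den <- 1 - tanh(beta * H) / (beta * H)
  u <- (1 - cosh(beta * s) / ch) / den
  psi <- ((s + H) - (sinh(beta * s) + sinh(beta * H)) / (beta * ch)) / den
  om <- beta * sinh(beta * s) / (ch * den)
  list(u = u, psi = psi, omega = om)
}

## Fully developed pulsatile state for a waveform of mean velocity
## coefficients, evaluated at transverse stations and times t.
## geometry = "tube": stations are radial fractions eta in [0,1], R given.
## geometry = "channel": stations are centred y in [-H, H].
## Returns list of matrices (station x time): u, psi, omega.
developed_pulsatile_state <- function(stations, t, waveform, nu,
                                      geometry = c("tube", "channel"),
                                      R = NULL, H = NULL) {
  geometry <- match.arg(geometry)
  Om <- 2 * pi / waveform$period
  ns <- length(stations); nt <- length(t)
  U <- matrix(0, ns, nt); PSI <- matrix(0, ns, nt); W <- matrix(0, ns, nt)
  ## steady (DC) component
  if (geometry == "tube") {
    eta <- stations
    U   <- U + waveform$a0 * 2 * (1 - eta^2) %o% rep(1, nt)
    PSI <- PSI + waveform$a0 * R^2 * (eta^2 - eta^4 / 2) %o% rep(1, nt)
    W   <- W + (4 * waveform$a0 * eta / R) %o% rep(1, nt)
  } else {
    s <- stations
    U   <- U + 1.5 * waveform$a0 * (1 - (s / H)^2) %o% rep(1, nt)
    PSI <- PSI + waveform$a0 * (1.5 * (s - s^3 / (3 * H^2)) + H) %o% rep(1, nt)
    W   <- W + (3 * waveform$a0 * s / H^2) %o% rep(1, nt)
  }
  K <- length(waveform$a)
  if (length(waveform$b) != K) stop("waveform coefficient length mismatch")
  for (k in seq_len(K)) {
    Vk <- complex(real = waveform$a[k], imaginary = -waveform$b[k])
    if (Mod(Vk) == 0) next
    om_k <- k * Om
    sh <- if (geometry == "tube")
      womersley_tube_shapes(stations, R, om_k, nu)
    else
      channel_shapes(stations, H, om_k, nu)
    ph <- exp(complex(real = 0, imaginary = om_k * t))  # e^{i k Om t}
    U   <- U + Re((Vk * sh$u) %o% ph)
    PSI <- PSI + Re((Vk * sh$psi) %o% ph)
    W   <- W + Re((Vk * sh$omega) %o% ph)
  }
  list(u = U, psi = PSI, omega = W)
}

#' Womersley closed-form axial velocity in a rigid tube
#'
#' Fully developed pulsatile axial velocity for a prescribed mean-velocity
#' waveform; the standard analytic oracle for pulsatile tube flow.
#'
#' @param r radial positions (m), `0 <= r <= R`
#' @param t times (s)
#' @param waveform a [fit_waveform()] / [waveform_from_coefficients()] object
#'   giving the cross-section-averaged velocity over the cycle
#' @param R tube radius (m)
#' @param nu kinematic viscosity (m^2/s)
#' @return matrix of u (m/s), `length(r)` x `length(t)`
#' @export
womersley_velocity <- function(r, t, waveform, R, nu) {
  stopifnot(all(r >= 0), all(r <= R + 1e-12))
  developed_pulsatile_state(r / R, t, waveform, nu, "tube", R = R)$u
}
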