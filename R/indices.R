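## Wall-based hemodynamic indices over the final cycle and time-averaged
## NO summaries.

trapz <- function(y, x) {
  if (length(x) < 2L) stop("need at least two samples for quadrature")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

check_series <- function(tau, times) {
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  if (ncol(tau) != length(times) || length(times) < 2L)
    stop("wall shear series must have one column per time sample (>= 2)")
  tau
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\tau_w| dt} by trapezoidal
#' quadrature over the supplied period.
#'
#' @param tau signed WSS series: vector (one point) or matrix (points x
#'   times), Pa
#' @param times time samples spanning exactly one period (s)
#' @return TAWSS per point (Pa)
#' @export
tawss <- function(tau, times) {
  tau <- check_series(tau, times)
  T <- times[length(times)] - times[1]
  apply(abs(tau), 1, trapz, x = times) / T
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{OSI = \frac{1}{2}\left(1 -
#'   \frac{|\int_0^T \tau_w dt|}{\int_0^T |\tau_w| dt}\right)}
#' 0 for unidirectional shear, 0.5 for perfectly reversing shear.
#' An identically zero series has no defined direction; `NA` is returned
#' with a warning for such points.
#'
#' @inheritParams tawss
#' @return OSI per point, in `[0, 0.5]`
#' @export
osi <- function(tau, times) {
  tau <- check_series(tau, times)
  num <- abs(apply(tau, 1, trapz, x = times))
  den <- apply(abs(tau), 1, trapz, x = times)
  out <- 0.5 * (1 - num / den)
  if (any(den == 0)) {
    warning("OSI undefined for identically zero shear series; returning NA")
    out[den == 0] <- NA_real_
  }
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time (RRT)
#'
#' `1 / ((1 - 2 OSI) TAWSS)`; infinite (flagged) where OSI reaches 0.5.
#' @param tawss_v TAWSS values (Pa), > 0
#' @param osi_v OSI values
#' @return RRT (1/Pa)
#' @export
rrt <- function(tawss_v, osi_v) {
  if (any(tawss_v <= 0, na.rm = TRUE)) stop("RRT requires TAWSS > 0")
  1 / ((1 - 2 * osi_v) * tawss_v)
}

#' Endothelial cell activation potential (ECAP)
#'
#' `OSI / TAWSS`.
#' @inheritParams rrt
#' @return ECAP (1/Pa)
#' @export
ecap <- function(tawss_v, osi_v) {
  if (any(tawss_v <= 0, na.rm = TRUE)) stop("ECAP requires TAWSS > 0")
  osi_v / tawss_v
}

#' Time-averaged wall shear stress gradient (TAWSSG)
#'
#' Time average of the magnitude of the surface-tangential gradient of the
#' WSS, computed by finite differences along the interface arc length. On
#' a 2D wall curve the full Cartesian gradient magnitude reduces to
#' `|d tau / d s|`.
#'
#' @param tau WSS series matrix (positions x times), Pa
#' @param s interface arc-length positions (m), >= 2 points
#' @param times time samples spanning one period (s)
#' @return TAWSSG per position (Pa/m)
#' @export
tawssg <- function(tau, s, times) {
  if (length(s) < 2L) stop("TAWSSG needs at least two interface points")
  tau <- check_series(tau, times)
  if (nrow(tau) != length(s)) stop("tau rows must match arc-length positions")
  ds <- d1_matrix(s)
  grad <- abs(as.matrix(ds %*% tau))
  T <- times[length(times)] - times[1]
  apply(grad, 1, trapz, x = times) / T
}

#' Time-averaged NO concentration (TAcNO)
#'
#' Time-averages the concentration series over the final cycle, then
#' spatially averages over the requested surface, line or section region
#' (optionally weighted, e.g. by face areas or segment lengths).
#'
#' @param conc concentration series: vector (steady/single point) or
#'   matrix (points x times), nM
#' @param times time samples (s); a single-column series is treated as
#'   already time-averaged
#' @param weights optional spatial weights
#' @return TAcNO (nM), a single number
#' @export
tacno <- function(conc, times = NULL, weights = NULL) {
  if (is.null(dim(conc))) conc <- matrix(conc, ncol = if (is.null(times)) 1 else length(times))
  if (nrow(conc) == 0L) stop("empty region for TAcNO")
  tavg <- if (ncol(conc) == 1L) conc[, 1]
  else {
    if (is.null(times) || length(times) != ncol(conc))
      stop("times must match the concentration series columns")
    T <- times[length(times)] - times[1]
    apply(conc, 1, trapz, x = times) / T
  }
  if (is.null(weights)) mean(tavg) else stats::weighted.mean(tavg, weights)
}

#' Compute the wall index field
#'
#' Evaluates TAWSS, OSI, RRT, ECAP and TAWSSG from a flow solution's
#' final-cycle WSS series, and (when an NO solution is supplied) the
#' pointwise time-averaged endothelial surface NO concentration, at every
#' interface point of every wall side.
#'
#' @param flow a `flow_solution`
#' @param no_sol optionally, the matching [solve_no()] solution
#' @return `index_field` data.frame: `side`, `s_mm`, `z_mm`, `TAWSS`,
#'   `OSI`, `RRT`, `ECAP`, `TAWSSG`, `TAcNO`
#' @export
compute_indices <- function(flow, no_sol = NULL) {
  wss <- extract_wss(flow)
  mesh <- flow$mesh
  out <- list()
  for (nm in names(wss$sides)) {
    sd <- wss$sides[[nm]]
    times <- wss$times
    if (length(times) < 2L) {        # steady solution: duplicate snapshot
      times <- c(0, 1)
      sd$tau <- cbind(sd$tau[, 1], sd$tau[, 1])
    }
    ta <- tawss(sd$tau, times)
    os <- osi(sd$tau, times)
    df <- data.frame(side = nm, s_mm = sd$s * 1e3, z_mm = mesh$z * 1e3,
                     TAWSS = ta, OSI = os,
                     RRT = rrt(ta, os), ECAP = ecap(ta, os),
                     TAWSSG = tawssg(sd$tau, sd$s, times),
                     TAcNO = NA_real_)
    if (!is.null(no_sol)) {
      side_key <- if (nm == "bottom") "lower" else names(mesh$walls)[1]
      cs <- no_sol$cs[[side_key]]
      tv <- no_sol$times
      face_tacno <- if (ncol(cs) == 1L) cs[, 1]
      else apply(cs, 1, trapz, x = tv) / (tv[length(tv)] - tv[1])
      ## faces -> nodes: average adjacent faces, copy at the ends
      nfc <- length(face_tacno)
      node_vals <- c(face_tacno[1],
                     (face_tacno[-nfc] + face_tacno[-1]) / 2,
                     face_tacno[nfc])
      df$TAcNO <- node_vals
    }
    out[[nm]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("index_field", "data.frame")
  res
}
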