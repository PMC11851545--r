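#' Fit a truncated Fourier series to an inlet velocity waveform
#'
#' Least-squares fit of sampled (time, velocity) pairs spanning one cardiac
#' period to
#' \deqn{v(t) = a_0 + \sum_{k=1}^{K} a_k \cos(k\Omega t) + b_k \sin(k\Omega t)}
#' with \eqn{\Omega = 2\pi/T}. This reproduces, in-package, the smoothing
#' and Fourier fitting conventionally applied to ultrasound-derived
#' velocity waveforms before they are imposed as inlet boundary conditions.
#'
#' @param samples data.frame with columns `time_s` and `velocity_m_per_s`
#'   (or a 2-column numeric matrix/data.frame), times strictly increasing
#'   and spanning one period
#' @param K number of harmonics (>= 1)
#' @param period the period T (s); defaults to the sample span
#' @return an object of class `waveform`: coefficients `a0`, `a`, `b`, the
#'   period, the retained source samples, and the fit residual RMS
#' @examples
#' t <- seq(0, 1, length.out = 64)
#' wf <- fit_waveform(data.frame(time_s = t, velocity_m_per_s = sin(2 * pi * t)),
#'                    K = 1, period = 1)
#' round(wf$b, 6)
#' @export
fit_waveform <- function(samples, K = 8L, period = NULL) {
  samples <- as.data.frame(samples)
  if (ncol(samples) < 2) stop("samples must have two columns (time, velocity)")
  t <- as.numeric(samples[[1]]); v <- as.numeric(samples[[2]])
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing")
  if (K < 1L) stop("K must be >= 1")
  if (length(t) < 2L * K + 1L)
    stop(sprintf("need at least 2K+1 = %d samples for K = %d harmonics",
                 2L * K + 1L, K))
  if (is.null(period)) period <- t[length(t)] - t[1]
  if (period <= 0) stop("period must be positive")
  om <- 2 * pi / period
  X <- cbind(1, do.call(cbind, lapply(seq_len(K), function(k)
    cbind(cos(k * om * t), sin(k * om * t)))))
  beta <- stats::lm.fit(X, v)$coefficients
  a <- beta[seq(2, 2 * K, by = 2)]
  b <- beta[seq(3, 2 * K + 1, by = 2)]
  resid <- v - as.vector(X %*% beta)
  structure(list(period = period, K = K,
                 a0 = unname(beta[1]), a = unname(a), b = unname(b),
                 samples = data.frame(time_s = t, velocity_m_per_s = v),
                 residual_rms = sqrt(mean(resid^2))),
            class = "waveform")
}

#' Evaluate a fitted waveform
#'
#' @param wf a [fit_waveform()] object
#' @param t times (s); the reconstruction is T-periodic
#' @return velocities (m/s)
#' @export
eval_waveform <- function(wf, t) {
  stopifnot(inherits(wf, "waveform"))
  om <- 2 * pi / wf$period
  v <- rep(wf$a0, length(t))
  for (k in seq_len(wf$K))
    v <- v + wf$a[k] * cos(k * om * t) + wf$b[k] * sin(k * om * t)
  v
}

#' Construct a waveform directly from Fourier coefficients
#'
#' @param period period T (s)
#' @param a0 mean velocity (m/s)
#' @param a,b cosine/sine harmonic coefficients (m/s), equal length
#' @export
waveform_from_coefficients <- function(period, a0, a = numeric(), b = numeric()) {
  stopifnot(length(a) == length(b), period > 0)
  structure(list(period = period, K = max(1L, length(a)),
                 a0 = a0,
                 a = if (length(a)) a else 0,
                 b = if (length(b)) b else 0,
                 samples = NULL, residual_rms = 0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> T = %g s, K = %d harmonics, mean %.4g m/s\n",
              x$period, x$K, x$a0))
  if (!is.null(x$residual_rms))
    cat(sprintf("  fit residual RMS %.3g m/s\n", x$residual_rms))
  invisible(x)
}

#' Peak velocity of a waveform over one period
#' @param wf a `waveform`
#' @param n evaluation resolution
#' @export
waveform_peak <- function(wf, n = 512L) {
  max(abs(eval_waveform(wf, seq(0, wf$period, length.out = n))))
}
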