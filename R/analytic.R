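#' Instantaneous phase and amplitude via the Hilbert analytic signal
#'
#' Computes the analytic representation `x(t) + i * H[x](t)` of a (band
#' limited) real signal by zeroing the negative frequencies of its Fourier
#' transform. The angle of the analytic signal is the instantaneous phase
#' (0 rad at positive peaks, cosine convention) and its magnitude the
#' instantaneous amplitude envelope.
#'
#' A constant-zero input has an amplitude of exactly 0 everywhere; the phase
#' is then undefined and returned as `NA`.
#'
#' @param x real signal, typically the output of [bandpass_filter()].
#' @return list with elements `phase` (radians in `(-pi, pi]`, `NA` where the
#'   envelope vanishes) and `amplitude` (same units as `x`, non-negative).
#' @examples
#' t <- seq(0, 2, by = 1 / 256)
#' a <- analytic_signal(cos(2 * pi * 5 * t))
#' @export
analytic_signal <- function(x) {
  if (!all(is.finite(x))) stop("input signal contains non-finite values")
  n <- length(x)
  if (n < 2) stop("signal too short")
  if (all(x == 0)) {
    return(list(phase = rep(NA_real_, n), amplitude = rep(0, n)))
  }
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  amp <- Mod(z)
  ph <- Arg(z)
  ph[amp == 0] <- NA_real_
  list(phase = ph, amplitude = amp)
}
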