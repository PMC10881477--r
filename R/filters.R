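# Butterworth band-pass design in zero-pole-gain form, converted to
# second-order sections (SOS). The transfer-function (b, a) form of a
# tenth-order band-pass with a 0.1 Hz corner at fs = 80 Hz is numerically
# ill-conditioned; the cascade of biquads is not.

#' Design a Butterworth band-pass filter in second-order sections
#'
#' Designs an analog Butterworth low-pass prototype, applies the low-pass to
#' band-pass transform and the bilinear transform (with frequency
#' pre-warping), and pairs conjugate pole pairs with one zero at z = 1 and
#' one at z = -1 per section.
#'
#' @param order prototype order; the digital band-pass has twice this order.
#' @param lo_hz,hi_hz corner frequencies in Hz.
#' @param fs sampling rate in Hz; `hi_hz` must lie below `fs / 2`.
#' @return An object of class `sos_filter`: a list with `sos` (matrix with
#'   columns b0, b1, b2, a0, a1, a2, one row per biquad) and the design
#'   parameters.
#' @export
butter_bandpass_sos <- function(order = 5, lo_hz = 0.1, hi_hz = 12, fs = 80) {
  stopifnot(order >= 1, lo_hz > 0, lo_hz < hi_hz, hi_hz < fs / 2)
  n <- as.integer(order)
  # analog prototype: n poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- 1
  # pre-warped band edges (bilinear transform with internal fs = 2)
  fs2 <- 4                      # 2 * internal sampling rate
  w <- 4 * tan(pi * c(lo_hz, hi_hz) / fs)
  w0 <- sqrt(w[1] * w[2])
  bw <- w[2] - w[1]
  # low-pass -> band-pass: each prototype pole splits into two
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  zbp <- rep(0 + 0i, n)
  gain <- gain * bw^n
  # bilinear transform
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zbp)))
  # pair poles into biquads: conjugate pairs, and real poles two at a time;
  # each section takes zeros {+1, -1}
  isreal <- abs(Im(pd)) < 1e-8 * (1 + Mod(pd))
  preal <- sort(Re(pd[isreal]))
  pcplx <- pd[!isreal & Im(pd) > 0]
  if (length(preal) %% 2L != 0L || length(preal) / 2 + length(pcplx) != n)
    stop("internal error: pole pairing failed")
  apoly <- c(
    lapply(pcplx, function(p) c(1, -2 * Re(p), Mod(p)^2)),
    if (length(preal)) lapply(seq(1, length(preal), by = 2), function(i)
      c(1, -(preal[i] + preal[i + 1]), preal[i] * preal[i + 1]))
  )
  apoly <- apoly[order(vapply(apoly, function(a) sqrt(abs(a[3])), numeric(1)))]
  sos <- t(vapply(seq_len(n), function(i) {
    b <- c(1, 0, -1)            # (z - 1)(z + 1)
    if (i == 1L) b <- b * gain
    c(b, apoly[[i]])
  }, numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  structure(list(sos = sos, order = n, lo_hz = lo_hz, hi_hz = hi_hz, fs = fs),
            class = "sos_filter")
}

#' @export
print.sos_filter <- function(x, ...) {
  cat(sprintf("Butterworth band-pass, order %d, %.3g-%.3g Hz at fs = %g Hz (%d SOS)\n",
              x$order, x$lo_hz, x$hi_hz, x$fs, nrow(x$sos)))
  invisible(x)
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_freqz <- function(filt, f, fs = filt$fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  z2 <- z1^2
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    h <- h * (s[1] + s[2] * z1 + s[3] * z2) / (s[4] + s[5] * z1 + s[6] * z2)
  }
  h
}

# Analytic squared magnitude of the designed digital filter: the analog
# band-pass Butterworth response evaluated at the pre-warped frequency.
butter_bandpass_gain2 <- function(f, order = 5, lo_hz = 0.1, hi_hz = 12, fs = 80) {
  w <- 4 * tan(pi * c(lo_hz, hi_hz) / fs)
  w0 <- sqrt(w[1] * w[2])
  bw <- w[2] - w[1]
  wd <- 4 * tan(pi * f / fs)
  1 / (1 + ((wd^2 - w0^2) / (bw * wd))^(2 * order))
}

# One biquad with steady-state initial conditions (the history before the
# first sample is assumed constant at x[1]); recursion runs in C via
# stats::filter.
biquad_filter <- function(x, b, a) {
  n <- length(x)
  x0 <- x[1]
  xl1 <- c(x0, x[-n])
  xl2 <- c(x0, x0, if (n > 2) x[1:(n - 2)])
  v <- b[1] * x + b[2] * xl1 + b[3] * xl2
  h1 <- sum(b) / (1 + a[2] + a[3])
  as.numeric(stats::filter(v, -a[2:3], method = "recursive",
                           init = c(h1 * x0, h1 * x0)))
}

sosfilt <- function(filt, x) {
  for (i in seq_len(nrow(filt$sos)))
    x <- biquad_filter(x, filt$sos[i, 1:3], filt$sos[i, 4:6])
  x
}

#' Zero-phase filtering through second-order sections
#'
#' Applies the SOS cascade forward and backward (odd-symmetric edge padding,
#' steady-state initial conditions), giving zero phase distortion and twice
#' the single-pass attenuation.
#'
#' @param filt an [butter_bandpass_sos()] object.
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
sosfiltfilt <- function(filt, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (2L * nrow(filt$sos) + 1L))
  if (padlen < 1L) stop("signal too short to filter")
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(front, x, back)
  y <- sosfilt(filt, ext)
  y <- rev(sosfilt(filt, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a normalised force trace
#'
#' The force processing chain applies a zero-phase fifth-order Butterworth
#' band-pass between 0.1 and 12 Hz, implemented in second-order sections, to
#' the continuous normalised force recording before cutting it into trials.
#'
#' @param trace normalised force samples.
#' @param fs sampling rate in Hz (default 80).
#' @param lo_hz,hi_hz pass-band corners in Hz.
#' @param order prototype filter order.
#' @return filtered trace of the same length.
#' @export
bandpass_force <- function(trace, fs = 80, lo_hz = 0.1, hi_hz = 12, order = 5) {
  if (fs <= 2 * hi_hz)
    stop("sampling rate too low: pass-band must lie below Nyquist")
  filt <- butter_bandpass_sos(order, lo_hz, hi_hz, fs)
  if (length(trace) <= 3L * (2L * nrow(filt$sos) + 1L) * 3L)
    stop("epoch too short to band-pass filter")
  sosfiltfilt(filt, trace)
}
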