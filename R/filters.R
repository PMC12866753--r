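# Butterworth band-pass design and zero-phase filtering.
#
# The sleep-scoring and spindle analyses need band-pass filtering with no phase
# distortion (events must stay aligned to the raw trace). No filter-design
# package is assumed: the design below is the textbook analog Butterworth
# prototype -> band-pass transform -> bilinear transform, and zero-phase
# filtering runs the resulting IIR forward and backward over an odd-symmetric
# signal extension (compiled inner loop).

#' Design a Butterworth band-pass filter
#'
#' @param order prototype (low-pass) order; the band-pass filter has `2*order`
#'   poles. Order 4 gives > 20 dB attenuation one octave outside the band for
#'   the bands used here.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < rate/2`.
#' @param rate sampling rate in Hz.
#' @return list with `sos` (sections x 6 matrix, columns b0 b1 b2 a0 a1 a2)
#'   and `poles` (discrete-time poles, used to size the zero-phase padding).
#'   Second-order sections keep narrow bands (e.g. 2-5 Hz at 1250 Hz)
#'   numerically stable where a flat transfer function would not be.
#' @keywords internal
butter_bandpass <- function(order, low, high, rate) {
  stopifnot(order >= 1, low > 0, high > low)
  if (high >= rate / 2)
    stop("band edge ", high, " Hz is at or above Nyquist (", rate / 2, " Hz)")
  # analog prototype poles on the unit circle (Butterworth), upper half plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # pre-warped band edges (normalized fs = 2)
  fs <- 2
  w1 <- 2 * fs * tan(pi * (low / (rate / 2)) / fs)
  w2 <- 2 * fs * tan(pi * (high / (rate / 2)) / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole splits into a pair around w0
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  kbp <- bw^order
  # bilinear transform; band-pass zeros (order at s=0) map to z=+1, the
  # bilinear degree completion adds order zeros at z=-1
  fs2 <- 2 * fs
  pd <- (fs2 + pbp) / (fs2 - pbp)
  kd <- kbp * Re(fs2^order / prod(fs2 - pbp))
  # biquad cascade: one conjugate pole pair per section, each section carrying
  # one zero at z=+1 and one at z=-1
  pu <- pd[Im(pd) > 0]
  stopifnot(length(pu) == order)
  gain <- abs(kd)^(1 / order) * (if (kd < 0) -1 else 1)
  sos <- t(vapply(seq_len(order), function(i) {
    pp <- pu[i]
    c(gain * c(1, 0, -1), 1, -2 * Re(pp), Mod(pp)^2)
  }, numeric(6)))
  list(sos = sos, poles = pd)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Pads with an odd-symmetric extension long enough for the slowest pole to
#' decay, filters forward and backward, and strips the padding, so that the
#' net phase response is zero and the effective attenuation is squared.
#'
#' @param filt list with `b`, `a` as returned by [butter_bandpass()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @keywords internal
filtfilt_iir <- function(filt, x) {
  r <- Mod(filt$poles)
  rmax <- max(r[r < 1], 0.5)
  padlen <- min(length(x) - 1L, max(12L, ceiling(-10 / log(rmax))))
  if (padlen < 1) stop("signal too short to filter")
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  y <- c(pre, x, post)
  sos <- filt$sos
  for (s in seq_len(nrow(sos)))
    y <- iir_filter_cpp(sos[s, 1:3], sos[s, 4:6], y)
  y <- rev(y)
  for (s in seq_len(nrow(sos)))
    y <- iir_filter_cpp(sos[s, 1:3], sos[s, 4:6], y)
  y <- rev(y)
  y[seq(padlen + 1, padlen + length(x))]
}

#' Band-pass filter a signal (zero phase)
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param band numeric length-2, `(low, high)` Hz.
#' @param order Butterworth prototype order (default 4).
#' @return filtered signal.
#' @export
bandpass_filter <- function(x, rate, band, order = 4) {
  stopifnot(length(band) == 2)
  filt <- butter_bandpass(order, band[1], band[2], rate)
  filtfilt_iir(filt, x)
}

#' Analytic-signal envelope via the Hilbert transform
#'
#' @param x numeric signal (band-limited for a meaningful envelope).
#' @return instantaneous amplitude `Mod(analytic(x))`.
#' @keywords internal
hilbert_envelope <- function(x) {
  n0 <- length(x)
  # pad to a 2,3,5-smooth length: R's mixed-radix FFT degrades to O(n*p) for a
  # large prime factor p; reflect-pad to avoid an edge discontinuity
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    pad <- n - n0
    x <- c(x, x[seq(n0 - 1, by = -1, length.out = min(pad, n0 - 1))],
           rep(x[1], max(0, pad - (n0 - 1))))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)[seq_len(n0)]
}

# Centered moving average with partial windows at the edges (cumsum based).
moving_average <- function(x, width) {
  width <- as.integer(max(1L, width))
  if (width >= length(x)) stop("smoothing window longer than signal")
  half <- width %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
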