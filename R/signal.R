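# Deterministic signal transforms shared by all pipeline stages.

#' Construct an event-count raster object
#'
#' @param counts neurons x frames matrix of non-negative event counts.
#' @param frame_duration frame duration in seconds (43 ms at the default
#'   multiplane imaging rate of 23.26 Hz).
#' @return object of class `sg_raster`.
#' @export
raster <- function(counts, frame_duration) {
  counts <- as.matrix(counts)
  if (!all(is.finite(counts)) || any(counts < 0))
    stop("raster counts must be finite and non-negative")
  if (frame_duration <= 0) stop("frame_duration must be positive")
  structure(list(counts = counts, frame_duration = frame_duration),
            class = "sg_raster")
}

#' @export
print.sg_raster <- function(x, ...) {
  cat(sprintf("<sg_raster> %d neurons x %d frames, frame %.1f ms\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$frame_duration))
  invisible(x)
}

#' Neuropil decontamination of a fluorescence trace
#'
#' Subtracts a fixed fraction of the surrounding-neuropil signal from each
#' ROI trace: `F_corrected = F_measured - coeff * F_neuropil`.
#'
#' @param f_measured,f_neuropil equal-length numeric traces.
#' @param coeff contamination coefficient (default 0.7).
#' @return corrected trace.
#' @export
neuropil_correct <- function(f_measured, f_neuropil, coeff = 0.7) {
  if (length(f_measured) != length(f_neuropil))
    stop("trace length mismatch")
  f_measured - coeff * f_neuropil
}

# unit-area Gaussian kernel truncated at +/- 4 SD (in frames)
gaussian_kernel <- function(sd_frames) {
  half <- max(1L, ceiling(4 * sd_frames))
  k <- dnorm(seq(-half, half), sd = sd_frames)
  k / sum(k)
}

#' Bin event times into a raster and smooth
#'
#' Events are counted in 0-based half-open frames `[k*dt, (k+1)*dt)` and each
#' neuron's count series is convolved with a unit-area Gaussian kernel
#' truncated at 4 SD, so total mass is conserved up to edge truncation.
#'
#' @param event_times list of per-neuron numeric vectors of event times (s).
#' @param frame_duration frame length in seconds.
#' @param smooth_sd Gaussian smoothing SD in seconds (default 0.1 s); 0
#'   disables smoothing.
#' @param n_frames total frames; defaults to cover the latest event.
#' @return [raster()] object.
#' @export
events_to_raster <- function(event_times, frame_duration, smooth_sd = 0.1,
                             n_frames = NULL) {
  if (smooth_sd < 0) stop("smooth_sd must be >= 0")
  all_t <- unlist(event_times, use.names = FALSE)
  if (length(all_t) && any(all_t < 0)) stop("negative event times")
  if (is.null(n_frames))
    n_frames <- max(1L, floor(max(c(all_t, 0)) / frame_duration) + 1L)
  counts <- t(vapply(event_times, function(tt) {
    tabulate(pmin(floor(tt / frame_duration) + 1L, n_frames), nbins = n_frames)
  }, numeric(n_frames)))
  if (smooth_sd > 0) {
    k <- gaussian_kernel(smooth_sd / frame_duration)
    half <- (length(k) - 1L) / 2L
    counts <- t(apply(counts, 1, function(row) {
      conv <- convolve(row, rev(k), type = "open")
      conv[seq(half + 1L, half + n_frames)]
    }))
    counts[counts < 0] <- 0  # convolution round-off
  }
  raster(counts, frame_duration)
}

#' Instantaneous band power / amplitude of a signal
#'
#' Zero-phase Butterworth band-pass, Hilbert-transform envelope, optional
#' squaring, then moving-average smoothing over the stated window.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param band `(low, high)` Hz, inside Nyquist.
#' @param smooth_window smoothing window in seconds (0 disables smoothing).
#' @param mode `"power"` (squared envelope, used for state scoring) or
#'   `"amplitude"` (envelope).
#' @return object of class `sg_bandpower`: list with `values`, `band`,
#'   `smoothing_window`, `source_rate`.
#' @export
band_power <- function(x, rate, band, smooth_window = 0, mode = "power") {
  mode <- match.arg(mode, c("power", "amplitude"))
  filtered <- bandpass_filter(x, rate, band)
  env <- hilbert_envelope(filtered)
  vals <- if (mode == "power") env^2 else env
  if (smooth_window > 0)
    vals <- moving_average(vals, round(smooth_window * rate))
  structure(list(values = vals, band = band, smoothing_window = smooth_window,
                 source_rate = rate),
            class = "sg_bandpower")
}

#' Mean of a signal over a half-open time window
#'
#' @param x numeric signal sampled at `rate`.
#' @param rate sampling rate, Hz.
#' @param window `(start, end)` seconds, half-open `[start, end)`, relative to
#'   the start of `x`.
#' @param normalizer `"raw"` or `"recording"` (divide by the mean over the
#'   whole of `x` before averaging, as used for evoked-potential amplitudes).
#' @return scalar mean.
#' @export
window_average <- function(x, rate, window, normalizer = "raw") {
  normalizer <- match.arg(normalizer, c("raw", "recording"))
  i0 <- floor(window[1] * rate) + 1L
  i1 <- ceiling(window[2] * rate)
  if (i1 < i0 || i0 < 1 || i1 > length(x)) stop("window outside signal")
  vals <- x[i0:i1]
  if (normalizer == "recording") vals <- vals / mean(x)
  mean(vals)
}

#' Z-score a frames x neurons activity matrix
#'
#' Columns (neurons) are centered and scaled by their SD over the whole
#' recording; zero-variance columns are left centered (scaled by 1).
#'
#' @param x frames x neurons matrix.
#' @return z-scored matrix.
#' @export
zscore_frames <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}
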