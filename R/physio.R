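# Synthetic physiological signals (LFP + EMG) matching the ground-truth state
# sequence: bimodal EMG high-frequency power across wake/sleep, hippocampal
# theta/delta elevated in REM, auditory-cortex sigma spindles during NREM,
# olfactory-bulb gamma elevated in wake.

# band-limited noise scaled per sample
state_band_noise <- function(n, rate, band, amp_by_sample) {
  bandpass_filter(rnorm(n), rate, band, order = 2) * amp_by_sample
}

# tapered-cosine (Tukey) window: cosine ramps over a fraction `a` of the
# support, flat plateau in between
tukey_window <- function(n, a = 0.25) {
  t <- seq(0, 1, length.out = n)
  e <- rep(1, n)
  lo <- t < a / 2
  hi <- t > 1 - a / 2
  e[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / a - 1)))
  e[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / a - 1)))
  e
}

#' Generate synthetic LFP/EMG channels for a session
#'
#' @param config a [session_config()].
#' @param truth ground truth from [generate_session()]; `state_sequence` and
#'   `spindle_intervals` drive the synthesis. Spindles (12 Hz bursts with a
#'   Hann envelope, amplitude `spindle_amp` times the NREM sigma-band
#'   background SD) are injected into the auditory-cortex channel during NREM
#'   only.
#' @param spindle_amp spindle amplitude in background-sigma SD units
#'   (default 5).
#' @return `sg_physio` list: `channels` (named list of numeric vectors: `emg`,
#'   `dhpc`, `aucx`, `ob`), `rate` (Hz), `duration_s`.
#' @export
generate_physio <- function(config, truth, spindle_amp = 5) {
  cfg <- config
  rate <- cfg$physio_rate
  if (rate < 2 * 300)
    stop("physio_rate below twice the highest synthesized band (300 Hz)")
  n_frames <- length(truth$state_sequence)
  dur <- n_frames / cfg$frame_rate
  n <- floor(dur * rate)
  # per-sample state from per-frame state
  fidx <- pmin(floor((seq_len(n) - 1) / rate * cfg$frame_rate) + 1L, n_frames)
  st <- truth$state_sequence[fidx]
  wake <- st == "wake"; rem <- st == "rem"; nrem <- st == "nrem"

  set.seed(stream_seed(cfg$seed, "physio"))
  # EMG: broadband noise, high amplitude in wake -> bimodal 50-300 Hz power
  emg <- rnorm(n) * ifelse(wake, 3, 0.8)

  # dorsal hippocampus: delta strong in NREM, theta strong in REM
  delta_amp <- ifelse(nrem, 4, ifelse(rem, 0.8, 1.2))
  theta_amp <- ifelse(rem, 4, ifelse(wake, 1.5, 0.8))
  dhpc <- state_band_noise(n, rate, c(2, 5), delta_amp) +
    state_band_noise(n, rate, c(5, 10), theta_amp) + 0.5 * rnorm(n)

  # auditory cortex: background + NREM delta + sigma spindles
  aucx_base <- rnorm(n)
  sigma_bg_sd <- sd(bandpass_filter(aucx_base, rate, c(10, 15)))
  aucx <- aucx_base + state_band_noise(n, rate, c(2, 5), ifelse(nrem, 2, 0.5))
  sp <- truth$spindle_intervals
  tvec <- (seq_len(n) - 1) / rate
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      sel <- which(tvec >= sp[i, 1] & tvec < sp[i, 2])
      if (!length(sel)) next
      env <- tukey_window(length(sel), 0.25)  # waxing-waning onto a plateau
      aucx[sel] <- aucx[sel] + spindle_amp * sigma_bg_sd * sqrt(2) *
        sin(2 * pi * 12 * tvec[sel]) * env
    }
  }

  # olfactory bulb: gamma (50-70 Hz) elevated in wake
  ob <- state_band_noise(n, rate, c(50, 70), ifelse(wake, 3, 0.5)) +
    0.5 * rnorm(n)

  structure(list(channels = list(emg = emg, dhpc = dhpc, aucx = aucx, ob = ob),
                 rate = rate, duration_s = dur),
            class = "sg_physio")
}

#' @export
print.sg_physio <- function(x, ...) {
  cat(sprintf("<sg_physio> %d channels (%s), %.1f s at %g Hz\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$duration_s, x$rate))
  invisible(x)
}
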