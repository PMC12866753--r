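# Two-step automated vigilance-state scoring, hypnogram utilities, spindle
# detection and event-related oscillation contrasts.
#
# Step 1 separates wake from sleep on smoothed (3 s) EMG 50-300 Hz power (or
# OB 50-70 Hz gamma power): a two-component Gaussian mixture is fit to the log
# power, each component density is rescaled to unit area, and the intersection
# abscissa between the two means is the threshold (low power = sleep). Step 2
# splits sleep into NREM/REM on the smoothed (2 s) hippocampal theta(5-10) /
# delta(2-5) power ratio with a single-Gaussian fit; values where the fit
# under-explains the empirical density mark REM. NREM/REM islets shorter than
# 3 s are merged into their surroundings.

# ---- two-component Gaussian mixture -----------------------------------------

fit_gmm2 <- function(x, n_restart = 3, max_iter = 200, tol = 1e-8) {
  best <- NULL
  for (r in seq_len(n_restart)) {
    qs <- quantile(x, c(0.25, 0.75), names = FALSE)
    mu <- qs + (r - 1) * 0.1 * diff(qs) * c(-1, 1)
    sg <- rep(sd(x) / 2, 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d2 <- w[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d1 / tot
      w <- c(mean(g), 1 - mean(g))
      mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
      sg <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                   sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
      sg <- pmax(sg, 1e-6 * sd(x))
      ll <- sum(log(tot))
      if (abs(ll - ll_old) < tol * abs(ll_old)) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(mu = mu, sigma = sg, w = w, ll = ll)
  }
  ord <- order(best$mu)
  list(mu = best$mu[ord], sigma = best$sigma[ord], w = best$w[ord],
       loglik = best$ll)
}

#' Threshold from the intersection of two fitted Gaussians
#'
#' Fits a two-component Gaussian mixture, rescales each component density to
#' unit area (mixture weights discarded), and returns the abscissa between the
#' two means where the densities intersect. `separation_ok` is FALSE when the
#' fitted components are not separable (Ashman's D below 2), i.e. when the
#' sample does not support a bimodal split.
#'
#' @param values numeric sample (>= 100 values).
#' @return list: `threshold`, `separation_ok`, `fit` (mu/sigma/w).
#' @export
bimodal_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need >= 100 samples")
  if (sd(values) == 0) stop("degenerate constant input")
  fit <- fit_gmm2(values)
  m1 <- fit$mu[1]; m2 <- fit$mu[2]; s1 <- fit$sigma[1]; s2 <- fit$sigma[2]
  # dnorm(x, m1, s1) == dnorm(x, m2, s2): quadratic in x
  if (abs(s1 - s2) < 1e-12 * (s1 + s2)) {
    thr <- (m1 + m2) / 2
  } else {
    a <- 1 / s2^2 - 1 / s1^2
    b <- 2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m2^2 / s2^2 - m1^2 / s1^2 + 2 * log(s2 / s1)
    disc <- b^2 - 4 * a * cc
    roots <- if (disc >= 0) (-b + c(1, -1) * sqrt(disc)) / (2 * a) else numeric(0)
    inside <- roots[roots >= min(m1, m2) & roots <= max(m1, m2)]
    thr <- if (length(inside)) inside[1] else {
      # fall back to a grid search between the means
      grid <- seq(min(m1, m2), max(m1, m2), length.out = 2001)
      grid[which.min(abs(dnorm(grid, m1, s1) - dnorm(grid, m2, s2)))]
    }
  }
  # bimodality evidence: the two-component fit must beat a single Gaussian
  # under BIC and the components must be separable (Ashman's D >= 2) --
  # either alone misfires on tight or mildly skewed unimodal samples
  n <- length(values)
  ll1 <- sum(dnorm(values, mean(values),
                   sd(values) * sqrt((n - 1) / n), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  d_ashman <- abs(m2 - m1) / sqrt((s1^2 + s2^2) / 2)
  list(threshold = thr, separation_ok = bic2 < bic1 && d_ashman >= 2,
       fit = fit)
}

# ---- hypnogram construction -------------------------------------------------

states_to_hypnogram <- function(states, rate) {
  n <- length(states)
  changes <- c(1L, which(states[-1] != states[-n]) + 1L)
  starts <- (changes - 1) / rate
  ends <- c(starts[-1], n / rate)
  data.frame(start_s = starts, end_s = ends, state = states[changes],
             stringsAsFactors = FALSE)
}

coalesce_hypnogram <- function(h) {
  if (nrow(h) < 2) return(h)
  keep <- c(TRUE, h$state[-1] != h$state[-nrow(h)])
  idx <- cumsum(keep)
  data.frame(start_s = tapply(h$start_s, idx, min),
             end_s = tapply(h$end_s, idx, max),
             state = h$state[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Merge NREM/REM intervals shorter than min_dur into the longer neighbor
# (ties -> preceding neighbor); wake intervals are never merged away.
merge_short_sleep <- function(h, min_dur = 3) {
  h <- coalesce_hypnogram(h)
  repeat {
    dur <- h$end_s - h$start_s
    short <- which(h$state %in% c("nrem", "rem") & dur < min_dur)
    if (!length(short)) break
    i <- short[which.min(dur[short])]
    left <- if (i > 1) dur[i - 1] else -Inf
    right <- if (i < nrow(h)) dur[i + 1] else -Inf
    if (left == -Inf && right == -Inf) break
    absorb <- if (left >= right) i - 1L else i + 1L
    h$state[i] <- h$state[absorb]
    h <- coalesce_hypnogram(h)
  }
  h
}

#' State of a hypnogram at given times
#'
#' Intervals are half-open `[start_s, end_s)`; the final interval also contains
#' its right edge.
#'
#' @param hypnogram data.frame with `start_s`, `end_s`, `state`.
#' @param t numeric times (s).
#' @return character vector of states (NA outside the scored span).
#' @export
hypnogram_state_at <- function(hypnogram, t) {
  idx <- findInterval(t, hypnogram$start_s)
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & (t < hypnogram$end_s[pmax(idx, 1)] |
                      (idx == nrow(hypnogram) &
                         t <= hypnogram$end_s[nrow(hypnogram)]))
  out[ok] <- hypnogram$state[idx[ok]]
  out
}

#' Automated two-step sleep scoring
#'
#' @param physio `sg_physio` object (channels `emg`, `dhpc`, and optionally
#'   `ob`).
#' @param use_ob score wake/sleep on olfactory-bulb gamma (50-70 Hz) power
#'   instead of EMG 50-300 Hz power (default FALSE).
#' @param state_rate temporal resolution of the scored state sequence, Hz
#'   (default 5; the hypnogram is built from this grid).
#' @return list: `hypnogram` (data.frame start_s/end_s/state, contiguous),
#'   `wake_threshold`, `rem_threshold`, `separation_ok`.
#' @export
score_session <- function(physio, use_ob = FALSE, state_rate = 5) {
  stopifnot(inherits(physio, "sg_physio"))
  rate <- physio$rate
  if (physio$duration_s < 60) stop("need >= 60 s of signal to score")
  ch <- if (use_ob) "ob" else "emg"
  if (is.null(physio$channels[[ch]])) stop("missing channel: ", ch)
  band <- if (use_ob) c(50, 70) else c(50, 300)

  pw <- band_power(physio$channels[[ch]], rate, band, smooth_window = 3)$values
  # decimate to the scoring grid
  step <- max(1L, round(rate / state_rate))
  grid <- seq(1L, length(pw), by = step)
  t_grid <- (grid - 1) / rate
  lp <- log(pw[grid] + .Machine$double.eps)
  thr <- bimodal_threshold(lp)
  # no bimodal evidence of sleep -> whole session scored wake (flagged via
  # separation_ok; the threshold is meaningless on a unimodal distribution)
  asleep <- if (thr$separation_ok) lp < thr$threshold else
    rep(FALSE, length(lp))

  states <- rep("wake", length(grid))
  rem_thr <- NA_real_
  if (any(asleep)) {
    if (is.null(physio$channels$dhpc)) stop("missing channel: dhpc")
    delta <- band_power(physio$channels$dhpc, rate, c(2, 5),
                        smooth_window = 2)$values
    theta <- band_power(physio$channels$dhpc, rate, c(5, 10),
                        smooth_window = 2)$values
    ratio <- (theta[grid] / pmax(delta[grid], .Machine$double.eps))[asleep]
    rem_thr <- rem_ratio_threshold(ratio)
    states[asleep] <- ifelse(ratio > rem_thr, "rem", "nrem")
  }
  h <- merge_short_sleep(states_to_hypnogram(states, state_rate))
  list(hypnogram = h, wake_threshold = thr$threshold, rem_threshold = rem_thr,
       separation_ok = thr$separation_ok)
}

# REM threshold on the theta/delta ratio: fit a single Gaussian to the sleep
# ratio distribution (robust location/scale so the NREM bulk dominates) and
# take the smallest value above the fitted mode where the fitted density drops
# below 50% of the kernel-smoothed empirical density, i.e. where the unimodal
# fit stops explaining the data. No such point -> no REM (+Inf).
rem_ratio_threshold <- function(ratio) {
  mu <- median(ratio)
  sg <- mad(ratio)
  if (sg == 0) return(Inf)
  dens <- density(ratio, n = 512)
  above <- dens$x > mu
  fitted <- dnorm(dens$x, mu, sg)
  bad <- above & fitted < 0.5 * dens$y & dens$y > 0.01 * max(dens$y)
  if (!any(bad)) return(Inf)
  dens$x[which(bad)[1]]
}

#' Awakening statistics from a hypnogram and trial table
#'
#' @param hypnogram data.frame start_s/end_s/state.
#' @param trials trial table with `onset_s`.
#' @param window seconds after sound onset in which a sleep-to-wake transition
#'   counts as a sound-evoked awakening (default 1).
#' @return list: `awakening_rate` (sleep-to-wake transitions per second of
#'   scored time), `sound_evoked_awakening_prob` (NA with `undefined = TRUE`
#'   when no presentation starts in sleep), `n_sleep_onsets`.
#' @export
awakening_stats <- function(hypnogram, trials, window = 1) {
  h <- coalesce_hypnogram(hypnogram)
  n_awak <- sum(h$state[-nrow(h)] %in% c("nrem", "rem") &
                  h$state[-1] == "wake")
  total <- max(h$end_s) - min(h$start_s)
  wake_starts <- h$start_s[h$state == "wake"]
  st <- hypnogram_state_at(h, trials$onset_s)
  in_sleep <- which(st %in% c("nrem", "rem"))
  if (!length(in_sleep)) {
    return(list(awakening_rate = n_awak / total,
                sound_evoked_awakening_prob = NA_real_, undefined = TRUE,
                n_sleep_onsets = 0L))
  }
  evoked <- vapply(trials$onset_s[in_sleep], function(on) {
    any(wake_starts > on & wake_starts <= on + window)
  }, logical(1))
  list(awakening_rate = n_awak / total,
       sound_evoked_awakening_prob = mean(evoked), undefined = FALSE,
       n_sleep_onsets = length(in_sleep))
}

# ---- spindles ---------------------------------------------------------------

#' Detect sigma-band spindles during NREM sleep
#'
#' The trace is band-pass filtered 10-15 Hz (zero phase) and restricted to
#' NREM samples; instantaneous amplitude is the element-wise square of the
#' filtered trace. Runs above mean + `threshold_sd` * SD (statistics over NREM
#' samples only) become candidate events; events separated by < 200 ms are
#' merged and events shorter than 400 ms or longer than 3 s are discarded.
#'
#' @param lfp numeric LFP trace.
#' @param rate sampling rate, Hz (>= 100).
#' @param hypnogram data.frame start_s/end_s/state.
#' @param threshold_sd threshold in SD units (default 2).
#' @return data.frame `start_s`, `end_s`, with attributes `threshold_sd`,
#'   `no_nrem` flag.
#' @export
detect_spindles <- function(lfp, rate, hypnogram, threshold_sd = 2) {
  if (rate < 100) stop("rate must be >= 100 Hz")
  t <- (seq_along(lfp) - 1) / rate
  nrem <- hypnogram_state_at(hypnogram, t) == "nrem"
  nrem[is.na(nrem)] <- FALSE
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (!any(nrem)) {
    attr(empty, "no_nrem") <- TRUE
    return(empty)
  }
  filt <- bandpass_filter(lfp, rate, c(10, 15))
  amp <- filt^2
  amp[!nrem] <- NA
  mu <- mean(amp, na.rm = TRUE)
  sg <- sd(amp, na.rm = TRUE)
  above <- !is.na(amp) & amp > mu + threshold_sd * sg
  ev <- runs_to_intervals(above, rate)
  if (nrow(ev)) {
    ev <- merge_close_events(ev, 0.2)
    dur <- ev$end_s - ev$start_s
    ev <- ev[dur >= 0.4 & dur <= 3, , drop = FALSE]
    rownames(ev) <- NULL
  }
  attr(ev, "threshold_sd") <- threshold_sd
  attr(ev, "no_nrem") <- FALSE
  ev
}

runs_to_intervals <- function(flag, rate) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = (starts[keep] - 1) / rate, end_s = ends[keep] / rate)
}

merge_close_events <- function(ev, max_gap) {
  if (nrow(ev) < 2) return(ev)
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    if (ev$start_s[i] - out$end_s[nrow(out)] < max_gap) {
      out$end_s[nrow(out)] <- ev$end_s[i]
    } else {
      out <- rbind(out, ev[i, ])
    }
  }
  out
}

# ---- event-related oscillation contrasts ------------------------------------

#' Band-power contrast around responsive vs non-responsive presentations
#'
#' For each labeled trial, mean band power of the auditory-cortex LFP in a
#' window of length `window` centered on the middle of the sound presentation.
#' The contrast is `(mean non-responsive - mean responsive) / mean responsive`.
#' When spindle events (or a hypnogram to detect them from) are supplied, also
#' returns the probability of a spindle overlapping each time bin relative to
#' sound onset.
#'
#' @param physio `sg_physio` object.
#' @param trials trial table (`onset_s`, `duration_s`, `trial_id`).
#' @param labels gating labels (data.frame with `trial_id`, `label`).
#' @param band `(low, high)` Hz.
#' @param window window length, s (default 1.5).
#' @param spindles optional spindle data.frame (`start_s`, `end_s`).
#' @param hypnogram optional hypnogram; used to detect spindles when
#'   `spindles` is NULL.
#' @param prob_bins breaks (s, onset-relative) for the spindle probability
#'   curve.
#' @return list: `contrast`, `mean_responsive`, `mean_nonresponsive`,
#'   `per_trial` data.frame, `spindle_prob` (data.frame time/probability or
#'   NULL).
#' @export
event_related_power <- function(physio, trials, labels, band, window = 1.5,
                                spindles = NULL, hypnogram = NULL,
                                prob_bins = seq(-2, 2.5, by = 0.25)) {
  stopifnot(inherits(physio, "sg_physio"))
  tl <- merge(trials, labels[, c("trial_id", "label")], by = "trial_id")
  if (!all(c("responsive", "non-responsive") %in% tl$label))
    stop("need trials of both labels")
  pw <- band_power(physio$channels$aucx, physio$rate, band,
                   smooth_window = 0)$values
  center <- tl$onset_s + tl$duration_s / 2
  vals <- vapply(center, function(cc) {
    w <- c(cc - window / 2, cc + window / 2)
    w[1] <- max(w[1], 0)
    w[2] <- min(w[2], physio$duration_s - 1 / physio$rate)
    window_average(pw, physio$rate, w)
  }, numeric(1))
  m_r <- mean(vals[tl$label == "responsive"])
  m_n <- mean(vals[tl$label == "non-responsive"])
  if (is.null(spindles) && !is.null(hypnogram))
    spindles <- detect_spindles(physio$channels$aucx, physio$rate, hypnogram)
  spindle_prob <- NULL
  if (!is.null(spindles)) {
    mids <- head(prob_bins, -1) + diff(prob_bins) / 2
    prob <- vapply(seq_along(mids), function(b) {
      lo <- tl$onset_s + prob_bins[b]
      hi <- tl$onset_s + prob_bins[b + 1]
      hit <- vapply(seq_along(lo), function(k) {
        any(spindles$start_s < hi[k] & spindles$end_s > lo[k])
      }, logical(1))
      mean(hit)
    }, numeric(1))
    spindle_prob <- data.frame(time_s = mids, probability = prob)
  }
  list(contrast = (m_n - m_r) / m_r, mean_responsive = m_r,
       mean_nonresponsive = m_n,
       per_trial = data.frame(trial_id = tl$trial_id, label = tl$label,
                              power = vals),
       spindle_prob = spindle_prob)
}
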