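# Synthetic session generator.
#
# Emulates the statistical structure the downstream analyses assume: a session
# of alternating 2-min silence / sound blocks across wake and NREM sleep,
# deconvolved event-count rasters with state-dependent multiplicative response
# gain, a zero-gain "gated" mixture component, low-rank spontaneous dynamics
# with population bursts largely orthogonal to evoked patterns, and full
# ground truth for recovery tests.

# Named RNG streams: one global seed, independent deterministic sub-seeds per
# stage, so stages can be re-run independently.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) %% 2147480009 + h * 7919 + 13) %% 2147480009)
}

#' Configuration of a synthetic imaging session
#'
#' Defaults mirror the recording protocol emulated by the generator: 60 sounds
#' of ~0.5 s with a 2 s inter-onset interval, presented once each inside 2-min
#' stimulation blocks that alternate with 2-min silence blocks, imaged at
#' 23.26 Hz (43 ms frames). Response gain is drawn per presentation, shared
#' across neurons; in NREM it is scaled by `nrem_gain_scale` and zeroed
#' ("gated") with probability `gate_prob_nrem` (`gate_prob_wake` in wake).
#'
#' @param n_neurons number of neurons.
#' @param n_sounds number of distinct sounds (default 60, in 6 categories of
#'   10).
#' @param presentations_per_sound_per_state presentations of each sound in each
#'   state (default 20).
#' @param frame_rate imaging frame rate, Hz (default 23.26).
#' @param sound_duration stimulus duration, s (default 0.5).
#' @param isi onset-to-onset interval within a stimulation block, s (default 2).
#' @param block_duration block length, s (default 120).
#' @param wake_gain_mean mean single-trial response gain in wake (default 1).
#' @param nrem_gain_scale multiplicative gain scale in NREM (default 0.5).
#' @param gate_prob_nrem,gate_prob_wake probability that a presentation is
#'   fully gated (gain 0) in each state (defaults 0.17 / 0.078).
#' @param spont_rank rank of the low-dimensional spontaneous dynamics
#'   (default 10).
#' @param evoked_overlap target cosine overlap of evoked pattern directions
#'   with the spontaneous subspace, in `[0, 1]` (default 0.2).
#' @param noise_sd per-frame additive noise SD, in events/frame (default 0.3).
#' @param seed integer master seed.
#' @param states states in which sounds are presented (default wake + NREM).
#' @param gain_sd SD of the per-presentation gain fluctuation (default 0.2).
#' @param baseline_rate mean baseline event rate, events/frame (default 0.1).
#' @param tuning_mean,tuning_sd mean and spread of tuning amplitudes,
#'   events/frame (defaults 1 and 0.8).
#' @param spont_strength scale of the leading spontaneous latent SD (default 1).
#' @param burst_rate rate of spontaneous population bursts, Hz (default 0.05).
#' @param n_rem_bouts,rem_bout_duration REM bouts carved out of NREM silence
#'   blocks (defaults 2 bouts of 30 s; set `n_rem_bouts = 0` for none).
#' @param physio_rate LFP/EMG sampling rate, Hz (default 1250).
#' @param quantize round rectified activity to integer counts (default TRUE;
#'   set FALSE for machine-precision recovery checks).
#' @return validated `sg_config` list.
#' @export
session_config <- function(n_neurons,
                           n_sounds = 60,
                           presentations_per_sound_per_state = 20,
                           frame_rate = 23.26,
                           sound_duration = 0.5,
                           isi = 2,
                           block_duration = 120,
                           wake_gain_mean = 1,
                           nrem_gain_scale = 0.5,
                           gate_prob_nrem = 0.17,
                           gate_prob_wake = 0.078,
                           spont_rank = 10,
                           evoked_overlap = 0.2,
                           noise_sd = 0.3,
                           seed = 1,
                           states = c("wake", "nrem"),
                           gain_sd = 0.2,
                           baseline_rate = 0.1,
                           tuning_mean = 1,
                           tuning_sd = 0.8,
                           spont_strength = 1,
                           burst_rate = 0.05,
                           n_rem_bouts = 2,
                           rem_bout_duration = 30,
                           physio_rate = 1250,
                           quantize = TRUE) {
  cfg <- as.list(environment())
  counts <- c(n_neurons, n_sounds, presentations_per_sound_per_state,
              spont_rank)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  probs <- c(gate_prob_nrem, gate_prob_wake)
  if (any(probs < 0 | probs > 1)) stop("gate probabilities must be in [0,1]")
  if (evoked_overlap < 0 || evoked_overlap > 1)
    stop("evoked_overlap must be in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_sounds * isi > block_duration)
    stop("presentations cannot fit: n_sounds * isi exceeds block_duration")
  if (spont_rank >= n_neurons)
    stop("spont_rank must be smaller than n_neurons")
  if (!all(states %in% c("wake", "nrem")))
    stop("states must be a subset of wake/nrem")
  class(cfg) <- "sg_config"
  cfg
}

# Tuning matrix with controlled overlap between evoked pattern directions and
# the spontaneous subspace: each sound's deviation direction is a unit mixture
# alpha * (in-span) + sqrt(1-alpha^2) * (out-of-span), entries rectified.
make_tuning <- function(cfg, Q) {
  n <- cfg$n_neurons
  alpha <- cfg$evoked_overlap
  tuning <- matrix(0, n, cfg$n_sounds)
  amp <- runif(cfg$n_sounds, 0.6, 1.4)
  for (s in seq_len(cfg$n_sounds)) {
    d <- rnorm(n)
    d_in <- Q %*% crossprod(Q, d)
    d_out <- d - d_in
    u <- alpha * d_in / sqrt(sum(d_in^2)) +
      sqrt(1 - alpha^2) * d_out / sqrt(sum(d_out^2))
    tuning[, s] <- pmax(0, cfg$tuning_mean +
                          amp[s] * cfg$tuning_sd * sqrt(n) * drop(u))
  }
  tuning
}

# Block schedule: per presentation round and state, one silence block followed
# by one stimulation block. Returns data.frame(start_s, duration, type, state).
make_blocks <- function(cfg) {
  rows <- list()
  t0 <- 0
  for (round in seq_len(cfg$presentations_per_sound_per_state)) {
    for (st in cfg$states) {
      for (ty in c("silence", "sound")) {
        rows[[length(rows) + 1L]] <-
          data.frame(start_s = t0, duration = cfg$block_duration,
                     type = ty, state = st, stringsAsFactors = FALSE)
        t0 <- t0 + cfg$block_duration
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic session
#'
#' Produces an event-count raster, a trial table and the full ground truth
#' (tuning matrix, per-trial gains and gated flags, per-frame state labels,
#' spontaneous loadings, spindle intervals). Identical seeds give bit-identical
#' output.
#'
#' @param config a [session_config()].
#' @return list with elements `raster` ([raster()]), `trials` (data.frame:
#'   trial_id, sound_id, category, intensity_db, onset_s, duration_s, state)
#'   and `truth` (list: tuning, trial_gain, gated, state_sequence,
#'   spont_loadings, latent_sd, spindle_intervals, baseline).
#' @export
generate_session <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "sg_config"))
  blocks <- make_blocks(cfg)
  total_s <- sum(blocks$duration)
  n_frames <- floor(total_s * cfg$frame_rate)
  n <- cfg$n_neurons

  # per-frame state labels, with REM bouts carved from NREM silence blocks
  set.seed(stream_seed(cfg$seed, "schedule"))
  frame_t <- (seq_len(n_frames) - 1) / cfg$frame_rate
  state_seq <- rep("wake", n_frames)
  for (i in seq_len(nrow(blocks))) {
    sel <- frame_t >= blocks$start_s[i] &
      frame_t < blocks$start_s[i] + blocks$duration[i]
    state_seq[sel] <- blocks$state[i]
  }
  rem_windows <- NULL
  if (cfg$n_rem_bouts > 0 && "nrem" %in% cfg$states) {
    cand <- which(blocks$type == "silence" & blocks$state == "nrem")
    cand <- head(cand, cfg$n_rem_bouts)
    for (i in cand) {
      mid <- blocks$start_s[i] + blocks$duration[i] / 2
      w <- c(mid - cfg$rem_bout_duration / 2, mid + cfg$rem_bout_duration / 2)
      state_seq[frame_t >= w[1] & frame_t < w[2]] <- "rem"
      rem_windows <- rbind(rem_windows, w)
    }
  }

  # trial schedule: every sound once per stimulation block, random order
  sound_blocks <- blocks[blocks$type == "sound", , drop = FALSE]
  trials <- do.call(rbind, lapply(seq_len(nrow(sound_blocks)), function(i) {
    ord <- sample.int(cfg$n_sounds)
    data.frame(sound_id = ord,
               onset_s = sound_blocks$start_s[i] +
                 (seq_len(cfg$n_sounds) - 1) * cfg$isi,
               state = sound_blocks$state[i],
               stringsAsFactors = FALSE)
  }))
  trials$trial_id <- seq_len(nrow(trials))
  trials$category <- sound_category(trials$sound_id, cfg$n_sounds)
  trials$intensity_db <- 70
  trials$duration_s <- cfg$sound_duration
  trials <- trials[, c("trial_id", "sound_id", "category", "intensity_db",
                       "onset_s", "duration_s", "state")]

  # spontaneous structure
  set.seed(stream_seed(cfg$seed, "spont"))
  Q <- qr.Q(qr(matrix(rnorm(n * cfg$spont_rank), n, cfg$spont_rank)))
  latent_sd <- cfg$spont_strength * seq_len(cfg$spont_rank)^(-0.25)
  phi <- 0.9
  Z <- matrix(rnorm(cfg$spont_rank * n_frames), cfg$spont_rank, n_frames)
  for (t in 2:n_frames)
    Z[, t] <- phi * Z[, t - 1] + sqrt(1 - phi^2) * Z[, t]
  # population bursts along the leading spontaneous direction
  n_bursts <- rbinom(1, n_frames, cfg$burst_rate / cfg$frame_rate)
  burst_frames <- sort(sample.int(n_frames, n_bursts))
  burst_kernel <- dnorm(seq(-12, 12), sd = 0.3 * cfg$frame_rate)
  burst_kernel <- 4 * burst_kernel / max(burst_kernel)
  burst_trace <- numeric(n_frames)
  for (bf in burst_frames) {
    idx <- bf + seq(-12, 12)
    ok <- idx >= 1 & idx <= n_frames
    burst_trace[idx[ok]] <- burst_trace[idx[ok]] + burst_kernel[ok]
  }
  Z[1, ] <- Z[1, ] + burst_trace
  Z <- Z * latent_sd

  set.seed(stream_seed(cfg$seed, "tuning"))
  tuning <- make_tuning(cfg, Q)
  baseline <- rgamma(n, shape = 2, rate = 2 / cfg$baseline_rate)

  # per-trial gains: coordinated across neurons, gated with state-dependent
  # probability
  set.seed(stream_seed(cfg$seed, "gains"))
  n_trials <- nrow(trials)
  gated <- logical(n_trials)
  gain <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    p_gate <- if (trials$state[k] == "nrem") cfg$gate_prob_nrem else
      cfg$gate_prob_wake
    gated[k] <- runif(1) < p_gate
    if (gated[k]) {
      gain[k] <- 0
    } else {
      g <- max(0, rnorm(1, cfg$wake_gain_mean, cfg$gain_sd))
      gain[k] <- if (trials$state[k] == "nrem") g * cfg$nrem_gain_scale else g
    }
  }

  # assemble raster
  set.seed(stream_seed(cfg$seed, "noise"))
  X <- matrix(baseline, n, n_frames) + Q %*% Z
  if (cfg$noise_sd > 0)
    X <- X + matrix(rnorm(n * n_frames, sd = cfg$noise_sd), n, n_frames)
  for (k in seq_len(n_trials)) {
    if (gain[k] == 0) next
    fr <- response_frames(cfg, trials$onset_s[k], n_frames)
    X[, fr] <- X[, fr] + gain[k] * tuning[, trials$sound_id[k]]
  }
  X <- pmax(X, 0)
  if (cfg$quantize) X <- round(X)

  # spindle ground truth: within NREM (excluding REM bouts), non-overlapping,
  # durations 0.5-2 s, enforced gaps so merge rules cannot fuse them
  set.seed(stream_seed(cfg$seed, "spindles"))
  spindles <- make_spindle_intervals(blocks, rem_windows, total_s)

  truth <- list(tuning = tuning, trial_gain = gain, gated = gated,
                state_sequence = state_seq, spont_loadings = Q,
                latent_sd = latent_sd, spindle_intervals = spindles,
                baseline = baseline, blocks = blocks)
  list(raster = raster(X, 1 / cfg$frame_rate), trials = trials, truth = truth,
       config = cfg)
}

# frames of the response window (stimulus duration + 250 ms), mapped with the
# same half-open convention as extract_responses so generated evoked activity
# and extracted responses cover identical frames
response_frames <- function(cfg, onset_s, n_frames) {
  f0 <- floor(onset_s * cfg$frame_rate) + 1L
  f1 <- floor((onset_s + cfg$sound_duration + 0.25) * cfg$frame_rate)
  f0:min(max(f1, f0), n_frames)
}

#' Sound category labels (6 groups of equal size)
#' @param sound_id integer sound ids.
#' @param n_sounds total number of sounds.
#' @return factor-like character vector of category names.
#' @export
sound_category <- function(sound_id, n_sounds = 60) {
  cats <- c("pure_tone", "chirp", "ramp", "sinusoid", "complex", "noise")
  per <- ceiling(n_sounds / length(cats))
  cats[pmin((sound_id - 1) %/% per + 1, length(cats))]
}

# Spindle ground truth at a physiological NREM density (~3/min); durations
# 0.6-2 s (within the detector's 0.4-3 s retention band), kept clear of REM
# bouts and of each other so the 200 ms merge rule cannot fuse distinct events.
make_spindle_intervals <- function(blocks, rem_windows, total_s,
                                   rate_hz = 0.05) {
  nrem_sil <- blocks[blocks$type == "silence" & blocks$state == "nrem", ,
                     drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(nrem_sil))) {
    b0 <- nrem_sil$start_s[i]
    b1 <- b0 + nrem_sil$duration[i]
    t <- b0 + rexp(1, rate_hz)
    while (t < b1 - 3) {
      dur <- runif(1, 0.6, 2)
      ok <- TRUE
      if (!is.null(rem_windows)) {
        for (r in seq_len(nrow(rem_windows)))
          if (t < rem_windows[r, 2] + 1 && t + dur > rem_windows[r, 1] - 1)
            ok <- FALSE
      }
      if (ok) out <- rbind(out, c(t, t + dur))
      t <- t + dur + 1 + rexp(1, rate_hz)
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("start_s", "end_s")
  out
}
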