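# Trial tables, window-averaged response vectors and per-sound firing-rate
# summaries.

#' Label a stimulus schedule with hypnogram states
#'
#' Each presentation gets the state of the hypnogram interval whose half-open
#' span contains its onset. Presentations starting in REM are kept but flagged
#' `excluded` so wake/NREM contrasts skip them.
#'
#' @param schedule data.frame with at least `sound_id`, `onset_s`,
#'   `duration_s`; optional `trial_id`, `category`, `intensity_db`.
#' @param hypnogram data.frame start_s/end_s/state.
#' @return trial table data.frame (trial_id, sound_id, category, intensity_db,
#'   onset_s, duration_s, state).
#' @export
build_trial_table <- function(schedule, hypnogram) {
  st <- hypnogram_state_at(hypnogram, schedule$onset_s)
  if (any(is.na(st))) stop("trial onset outside hypnogram span")
  out <- data.frame(
    trial_id = if (is.null(schedule$trial_id)) seq_len(nrow(schedule)) else
      schedule$trial_id,
    sound_id = schedule$sound_id,
    category = if (is.null(schedule$category))
      sound_category(schedule$sound_id) else schedule$category,
    intensity_db = if (is.null(schedule$intensity_db)) NA_real_ else
      schedule$intensity_db,
    onset_s = schedule$onset_s,
    duration_s = schedule$duration_s,
    state = ifelse(st == "rem", "excluded", st),
    stringsAsFactors = FALSE)
  if (is.unsorted(out$onset_s, strictly = TRUE))
    stop("trial onsets must be strictly increasing")
  out
}

#' Extract trial-aligned response and baseline matrices
#'
#' Per trial and neuron, the mean event rate (events/s) over the response
#' window (onset to sound offset + 250 ms) and over the pre-onset baseline
#' window. Frames are assigned by half-open overlap with the windows. Trials
#' whose response window is truncated by the session end are dropped (logged
#' in the `dropped` attribute).
#'
#' @param raster [raster()] object.
#' @param trials trial table.
#' @param baseline_window baseline length in seconds before onset (default
#'   0.5).
#' @return `sg_responses` list: `responses`, `baselines` (trials x neurons,
#'   rates in events/s), `trials` (possibly reduced trial table), `window`
#'   (onset-relative response window).
#' @export
extract_responses <- function(raster, trials, baseline_window = 0.5) {
  stopifnot(inherits(raster, "sg_raster"))
  dt <- raster$frame_duration
  n_frames <- ncol(raster$counts)
  resp_end <- trials$duration_s + 0.25
  f_on <- floor(trials$onset_s / dt) + 1L
  f_off <- floor((trials$onset_s + resp_end) / dt)
  f_b0 <- pmax(1L, floor((trials$onset_s - baseline_window) / dt) + 1L)
  f_b1 <- pmax(f_b0, f_on - 1L)
  keep <- f_off <= n_frames & f_on >= 1L
  dropped <- trials$trial_id[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " trial(s) truncated by session end")
  trials <- trials[keep, , drop = FALSE]
  f_on <- f_on[keep]; f_off <- f_off[keep]
  f_b0 <- f_b0[keep]; f_b1 <- f_b1[keep]
  n_tr <- nrow(trials)
  n <- nrow(raster$counts)
  responses <- matrix(0, n_tr, n)
  baselines <- matrix(0, n_tr, n)
  for (k in seq_len(n_tr)) {
    responses[k, ] <- rowMeans(raster$counts[, f_on[k]:f_off[k], drop = FALSE]) / dt
    baselines[k, ] <- rowMeans(raster$counts[, f_b0[k]:f_b1[k], drop = FALSE]) / dt
  }
  structure(list(responses = responses, baselines = baselines,
                 trials = trials, window = c(0, resp_end[1]),
                 dropped = dropped),
            class = "sg_responses")
}

#' Per-sound and per-state response summaries
#'
#' @param resp `sg_responses` from [extract_responses()].
#' @param states states to summarize (default wake and NREM).
#' @return list: `per_sound` (data.frame sound_id/state/mean_rate of
#'   baseline-subtracted population response, NA-flagged when a cell has < 2
#'   presentations), `per_neuron` (data.frame neuron/state/p_nonzero/
#'   amp_nonzero), `state_ratio` (overall NREM/wake mean-response ratio).
#' @export
tuning_summary <- function(resp, states = c("wake", "nrem")) {
  trials <- resp$trials
  delta <- resp$responses - resp$baselines
  pop <- rowMeans(delta)
  per_sound <- expand.grid(sound_id = sort(unique(trials$sound_id)),
                           state = states, stringsAsFactors = FALSE)
  per_sound$mean_rate <- NA_real_
  per_sound$n <- 0L
  for (i in seq_len(nrow(per_sound))) {
    sel <- trials$sound_id == per_sound$sound_id[i] &
      trials$state == per_sound$state[i]
    per_sound$n[i] <- sum(sel)
    if (sum(sel) >= 2) per_sound$mean_rate[i] <- mean(pop[sel])
  }
  per_neuron <- do.call(rbind, lapply(states, function(st) {
    sel <- trials$state == st
    nz <- resp$responses[sel, , drop = FALSE] > 0
    amp <- resp$responses[sel, , drop = FALSE]
    amp[!nz] <- NA
    data.frame(neuron = seq_len(ncol(nz)), state = st,
               p_nonzero = colMeans(nz),
               amp_nonzero = suppressWarnings(colMeans(amp, na.rm = TRUE)))
  }))
  means <- vapply(states, function(st) mean(pop[trials$state == st]),
                  numeric(1))
  ratio <- if (all(c("wake", "nrem") %in% states) && means["wake"] > 0)
    unname(means["nrem"] / means["wake"]) else NA_real_
  list(per_sound = per_sound, per_neuron = per_neuron, state_ratio = ratio)
}

#' Rescale a NREM per-sound response curve to the wake maximum
#'
#' Multiplies the NREM vector by `max(wake) / nrem[argmax(wake)]`, so that at
#' the sound driving the largest wake response the rescaled NREM value equals
#' the wake maximum.
#'
#' @param wake,nrem equal-length per-sound mean response vectors.
#' @return rescaled NREM vector.
#' @export
rescale_to_wake_max <- function(wake, nrem) {
  stopifnot(length(wake) == length(nrem))
  i <- which.max(wake)
  if (wake[i] <= 0) stop("wake maximum must be positive")
  if (nrem[i] <= 0) stop("NREM value at the wake argmax must be positive")
  nrem * wake[i] / nrem[i]
}
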