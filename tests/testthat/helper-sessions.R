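# Shared fixtures: sessions are generated once per test run and memoised, so
# several test files can reuse the same synthetic recordings.

.sg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sg_cache))
    assign(key, force(expr), envir = .sg_cache)
  get(key, envir = .sg_cache)
}

# small two-state session with default gating/gain world
small_session <- function() {
  cached("small", {
    cfg <- session_config(n_neurons = 120, n_sounds = 20,
                          presentations_per_sound_per_state = 8,
                          block_duration = 40, seed = 3)
    s <- generate_session(cfg)
    s$resp <- extract_responses(s$raster, s$trials)
    s
  })
}

# noise-free deterministic session (exactness oracles)
noisefree_session <- function() {
  cached("noisefree", {
    cfg <- session_config(n_neurons = 40, n_sounds = 8,
                          presentations_per_sound_per_state = 4,
                          block_duration = 20, seed = 7,
                          gate_prob_nrem = 0, gate_prob_wake = 0,
                          gain_sd = 0, noise_sd = 0, spont_strength = 0,
                          burst_rate = 0, n_rem_bouts = 0, quantize = FALSE)
    s <- generate_session(cfg)
    s$resp <- extract_responses(s$raster, s$trials)
    s
  })
}

# scored-physio session (sleep scoring + spindles)
physio_session <- function() {
  cached("physio", {
    cfg <- session_config(n_neurons = 30, n_sounds = 10,
                          presentations_per_sound_per_state = 4,
                          block_duration = 60, seed = 21,
                          n_rem_bouts = 2, rem_bout_duration = 20)
    s <- generate_session(cfg)
    s$physio <- generate_physio(cfg, s$truth)
    s
  })
}

# hand-built response container (unit tests that need exact control)
manual_responses <- function(responses, baselines = NULL, sound_id,
                             state = NULL, onset_s = NULL) {
  n_tr <- nrow(responses)
  if (is.null(baselines)) baselines <- matrix(0, n_tr, ncol(responses))
  if (is.null(state)) state <- rep("wake", n_tr)
  if (is.null(onset_s)) onset_s <- seq_len(n_tr) * 2
  structure(list(
    responses = responses, baselines = baselines,
    trials = data.frame(trial_id = seq_len(n_tr), sound_id = sound_id,
                        category = "complex", intensity_db = 70,
                        onset_s = onset_s, duration_s = 0.5, state = state,
                        stringsAsFactors = FALSE),
    window = c(0, 0.75), dropped = integer(0)),
    class = "sg_responses")
}

# interval overlap helpers for spindle recall/precision
spindle_recall <- function(truth, detected) {
  if (nrow(truth) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i)
    any(detected$start_s < truth[i, 2] & detected$end_s > truth[i, 1]),
    logical(1)))
}

spindle_precision <- function(truth, detected) {
  if (nrow(detected) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(detected)), function(i)
    any(truth[, 1] < detected$end_s[i] & truth[, 2] > detected$start_s[i]),
    logical(1)))
}
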