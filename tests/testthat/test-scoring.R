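test_that("bimodal threshold finds the intersection of unit-area Gaussians", {
  set.seed(1)
  x <- c(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  res <- bimodal_threshold(x)
  expect_lt(abs(res$threshold - 5), 0.25)  # equal variances -> midpoint
  expect_true(res$separation_ok)

  # unequal variances: numeric root of the unit-area density equality, found
  # by grid search on the same fitted parameters
  set.seed(2)
  y <- c(rnorm(3000, 0, 1), rnorm(3000, 6, 2))
  res2 <- bimodal_threshold(y)
  f <- res2$fit
  grid <- seq(f$mu[1], f$mu[2], length.out = 20001)
  oracle <- grid[which.min(abs(dnorm(grid, f$mu[1], f$sigma[1]) -
                                 dnorm(grid, f$mu[2], f$sigma[2])))]
  expect_equal(res2$threshold, oracle, tolerance = 1e-3)

  set.seed(3)
  expect_false(bimodal_threshold(rnorm(1000))$separation_ok)
  expect_error(bimodal_threshold(rep(1, 200)), "degenerate")
  expect_error(bimodal_threshold(rnorm(50)), ">= 100")
})

test_that("scored hypnogram agrees with ground truth", {
  s <- physio_session()
  sc <- score_session(s$physio)
  expect_true(sc$separation_ok)
  h <- sc$hypnogram
  # partition of the scored span: contiguous, non-overlapping
  expect_equal(h$start_s[-1], h$end_s[-nrow(h)])
  expect_equal(min(h$start_s), 0)
  dur <- h$end_s - h$start_s
  expect_true(all(dur[h$state %in% c("nrem", "rem")] >= 3))
  ft <- (seq_along(s$truth$state_sequence) - 1) / s$config$frame_rate
  pred <- hypnogram_state_at(h, ft)
  expect_gt(mean(pred == s$truth$state_sequence, na.rm = TRUE), 0.95)
})

test_that("all-wake physio scores as a single wake interval", {
  cfg <- session_config(n_neurons = 10, n_sounds = 5,
                        presentations_per_sound_per_state = 2,
                        block_duration = 30, seed = 33, states = "wake",
                        n_rem_bouts = 0, spont_rank = 3)
  s <- generate_session(cfg)
  ph <- generate_physio(cfg, s$truth)
  sc <- score_session(ph)
  expect_identical(sc$hypnogram$state, "wake")
  expect_equal(nrow(sc$hypnogram), 1)
})

test_that("short REM islets are merged away by the 3 s rule", {
  # 2 s REM islet inside NREM: absorbed into the longer neighbor
  states <- c(rep("wake", 50), rep("nrem", 100), rep("rem", 10),
              rep("nrem", 100))
  h <- sleepgeom:::merge_short_sleep(
    sleepgeom:::states_to_hypnogram(states, 5))
  expect_false("rem" %in% h$state)
  expect_equal(nrow(h), 2)
  # ties and longer islets survive
  states2 <- c(rep("nrem", 100), rep("rem", 20), rep("nrem", 100))
  h2 <- sleepgeom:::merge_short_sleep(
    sleepgeom:::states_to_hypnogram(states2, 5))
  expect_true("rem" %in% h2$state)
})

test_that("score_session is invariant to affine EMG rescaling", {
  s <- physio_session()
  ph2 <- s$physio
  ph2$channels$emg <- 7.3 * ph2$channels$emg
  h1 <- score_session(s$physio)$hypnogram
  h2 <- score_session(ph2)$hypnogram
  expect_equal(h1, h2)
})

test_that("awakening statistics match direct counting and a loop oracle", {
  h <- data.frame(start_s = c(0, 10), end_s = c(10, 20),
                  state = c("nrem", "wake"))
  tr <- data.frame(trial_id = 1:2, onset_s = c(9.5, 2))
  a <- awakening_stats(h, tr)
  expect_equal(a$sound_evoked_awakening_prob, 0.5)
  expect_equal(a$awakening_rate, 1 / 20)

  # all-sleep hypnogram: no transitions -> probability 0
  h0 <- data.frame(start_s = c(0, 50), end_s = c(50, 100),
                   state = c("nrem", "rem"))
  a0 <- awakening_stats(h0, tr)
  expect_equal(a0$sound_evoked_awakening_prob, 0)

  # random hypnogram + 1000 trials vs exhaustive loop
  set.seed(14)
  bounds <- sort(runif(19, 0, 100))
  hr <- data.frame(start_s = c(0, bounds), end_s = c(bounds, 100),
                   state = sample(c("wake", "nrem", "rem"), 20, TRUE))
  trr <- data.frame(trial_id = 1:1000, onset_s = sort(runif(1000, 0, 99)))
  ar <- awakening_stats(hr, trr)
  st_at <- function(t) hr$state[max(which(hr$start_s <= t))]
  sleep_on <- vapply(trr$onset_s, function(t) st_at(t) != "wake", logical(1))
  wake_starts <- hr$start_s[hr$state == "wake"]
  ev <- vapply(trr$onset_s, function(t)
    any(wake_starts > t & wake_starts <= t + 1), logical(1))
  expect_identical(ar$sound_evoked_awakening_prob,
                   mean(ev[sleep_on]))
  n_tr <- sum(hr$state[-nrow(hr)] != "wake" & hr$state[-1] == "wake")
  expect_identical(ar$awakening_rate, n_tr / 100)
})

test_that("spindle detection obeys threshold, merge and duration rules", {
  # background: steady low-amplitude sigma oscillation plus faint noise, so
  # that the background never crosses the mean + 2 SD level and the merge /
  # duration rules alone decide the outcome
  set.seed(6)
  rate <- 1000
  n <- 100 * rate
  tvec <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * 12 * tvec) + rnorm(n, sd = 0.05)
  sig_sd <- sd(bandpass_filter(x, rate, c(10, 15)))
  inject <- function(x, t0, dur, amp, smooth = FALSE) {
    sel <- tvec >= t0 & tvec < t0 + dur
    # smooth (Hann) onset/offset where requested: rectangular edges ring
    # through the 10-15 Hz filter for ~0.25 s and would physically lengthen
    # a short burst past the duration gate
    env <- if (smooth) sin(pi * seq_len(sum(sel)) / sum(sel))^2 else 1
    x[sel] <- x[sel] + amp * sig_sd * sin(2 * pi * 12 * tvec[sel]) * env
    x
  }
  all_nrem <- data.frame(start_s = 0, end_s = 100, state = "nrem")
  # 1 s burst at 5x background SD -> exactly one event overlapping it
  x1 <- inject(x, 50, 1, 5)
  ev1 <- detect_spindles(x1, rate, all_nrem)
  hit <- ev1$start_s < 51 & ev1$end_s > 50
  expect_equal(sum(hit), 1)
  # 0.3 s burst -> discarded by the 400 ms rule
  ev2 <- detect_spindles(inject(x, 50, 0.3, 5, smooth = TRUE), rate,
                         all_nrem)
  expect_false(any(ev2$start_s < 50.4 & ev2$end_s > 49.9))
  # two 0.5 s bursts separated by 0.15 s -> merged into one event
  x3 <- inject(inject(x, 50, 0.5, 5), 50.65, 0.5, 5)
  ev3 <- detect_spindles(x3, rate, all_nrem)
  inside <- ev3[ev3$start_s < 51.2 & ev3$end_s > 50, ]
  expect_equal(nrow(inside), 1)
  expect_gt(inside$end_s - inside$start_s, 1)
  # post-filter invariants hold for whatever else was detected
  for (ev in list(ev1, ev2, ev3)) {
    if (nrow(ev) == 0) next
    dur <- ev$end_s - ev$start_s
    expect_true(all(dur >= 0.4 - 1e-9 & dur <= 3 + 1e-9))
    if (nrow(ev) > 1)
      expect_true(all(ev$start_s[-1] - ev$end_s[-nrow(ev)] >= 0.2 - 1e-9))
  }
  # no NREM -> flagged empty result
  ev0 <- detect_spindles(x1, rate,
                         data.frame(start_s = 0, end_s = 100, state = "wake"))
  expect_equal(nrow(ev0), 0)
  expect_true(attr(ev0, "no_nrem"))
})

test_that("planted spindles are recovered from the synthetic session", {
  s <- physio_session()
  sc <- score_session(s$physio)
  sp <- detect_spindles(s$physio$channels$aucx, s$physio$rate, sc$hypnogram)
  expect_gte(spindle_recall(s$truth$spindle_intervals, sp), 0.9)
  expect_gte(spindle_precision(s$truth$spindle_intervals, sp), 0.9)
})

test_that("event-related power contrast reflects constructed sigma power", {
  cfg <- session_config(n_neurons = 10, n_sounds = 6,
                        presentations_per_sound_per_state = 3,
                        block_duration = 18, isi = 3, seed = 44,
                        states = "nrem", n_rem_bouts = 0, spont_rank = 3)
  s <- generate_session(cfg)
  ph <- generate_physio(cfg, s$truth)
  rate <- ph$rate
  tl <- s$trials
  # label half the trials non-responsive and double sigma amplitude there
  labels <- data.frame(trial_id = tl$trial_id,
                       label = rep(c("responsive", "non-responsive"),
                                   length.out = nrow(tl)))
  tvec <- (seq_along(ph$channels$aucx) - 1) / rate
  for (k in which(labels$label == "non-responsive")) {
    sel <- tvec >= tl$onset_s[k] - 0.75 & tvec < tl$onset_s[k] + 1.25
    ph$channels$aucx[sel] <- ph$channels$aucx[sel] +
      sin(2 * pi * 12 * tvec[sel])
  }
  res <- event_related_power(ph, tl, labels, band = c(10, 15))
  expect_gt(res$contrast, 0.5)
  # identical statistics -> contrast near 0
  labels2 <- labels
  labels2$label <- rep(c("responsive", "non-responsive"),
                       each = nrow(tl) / 2)[order(rep(1:2, nrow(tl) / 2))]
  ph0 <- generate_physio(cfg, s$truth)
  res0 <- event_related_power(ph0, tl, labels, band = c(50, 70))
  expect_lt(abs(res0$contrast), 0.2)
  # no spindles anywhere -> probability curve identically zero
  res_sp <- event_related_power(ph0, tl, labels, band = c(10, 15),
                                spindles = data.frame(start_s = numeric(0),
                                                      end_s = numeric(0)))
  expect_true(all(res_sp$spindle_prob$probability == 0))
})
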