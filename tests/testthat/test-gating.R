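test_that("templates average the strongest 30% of trials", {
  # 10 trials, intensities 1..10 -> template = mean of trials 8, 9, 10
  set.seed(71)
  base <- matrix(runif(10 * 6), 10, 6)
  x <- base * seq(0.5, 5, length.out = 10)  # increasing intensity
  resp <- manual_responses(x, sound_id = rep(1, 10))
  tm <- build_templates(resp, n_sounds = 1, states = "wake")
  intensity <- rowMeans(x)
  top3 <- order(-intensity)[1:3]
  expect_equal(tm[["1"]], colMeans(x[top3, ]))
  # all trials identical -> template equals any trial vector
  resp_id <- manual_responses(matrix(rep(1:6, each = 10), 10, 6),
                              sound_id = rep(1, 10))
  tm_id <- build_templates(resp_id, n_sounds = 1, states = "wake")
  expect_equal(tm_id[["1"]], as.numeric(1:6))
})

test_that("noise-free templates are proportional to tuning columns", {
  s <- noisefree_session()
  tm <- build_templates(s$resp, n_sounds = 4)
  for (sid in names(tm)) {
    tun <- s$truth$tuning[, as.integer(sid)]
    cc <- sum(tm[[sid]] * tun) / sqrt(sum(tm[[sid]]^2) * sum(tun^2))
    expect_equal(cc, 1, tolerance = 1e-8)
  }
})

test_that("bootstrap labels separate template-like from orthogonal trials", {
  set.seed(72)
  n <- 200
  tmpl <- abs(rnorm(n, 1, 0.5))
  templates <- list("1" = tmpl)
  # trial = template (all entries positive) -> responsive
  resp1 <- manual_responses(matrix(tmpl, 1, n), sound_id = 1)
  lab1 <- label_trials(resp1, templates, n_boot = 400, seed = 1)
  expect_identical(lab1$label, "responsive")
  # zero-mean noise trials -> non-responsive in >= 85% of seeded repeats
  hits <- 0
  for (seed in 1:20) {
    set.seed(1000 + seed)
    resp0 <- manual_responses(matrix(rnorm(n, 0, 1), 1, n), sound_id = 1)
    lab0 <- label_trials(resp0, templates, n_boot = 400, seed = seed)
    hits <- hits + (lab0$label == "non-responsive")
  }
  expect_gte(hits, 17)
  # zero trial vector -> non-responsive by convention, counted
  respz <- manual_responses(matrix(0, 1, n), sound_id = 1)
  labz <- label_trials(respz, templates, n_boot = 50, seed = 1)
  expect_identical(labz$label, "non-responsive")
  expect_equal(attr(labz, "zero_vectors"), 1L)
})

test_that("labels are deterministic and scale-invariant", {
  s <- small_session()
  tm <- build_templates(s$resp, n_sounds = 4)
  la <- label_trials(s$resp, tm, n_boot = 300, seed = 5)
  lb <- label_trials(s$resp, tm, n_boot = 300, seed = 5)
  expect_identical(la, lb)
  scaled <- s$resp
  scaled$responses <- 3 * scaled$responses
  scaled$baselines <- 3 * scaled$baselines
  tms <- build_templates(scaled, n_sounds = 4)
  ls <- label_trials(scaled, tms, n_boot = 300, seed = 5)
  expect_identical(la$label, ls$label)
})

test_that("planted gate probabilities are recovered within binomial error", {
  s <- small_session()
  tm <- build_templates(s$resp)
  lab <- label_trials(s$resp, tm, n_boot = 500, seed = 6)
  gs <- gating_summary(lab, s$resp, tm, seed = 7)
  for (st in c("wake", "nrem")) {
    p <- if (st == "nrem") s$config$gate_prob_nrem else s$config$gate_prob_wake
    n <- sum(lab$state == st)
    expect_lt(abs(gs$fraction_nonresponsive[[st]] - p),
              3 * sqrt(p * (1 - p) / n))
  }
  # non-responsive trials have near-zero baseline-subtracted amplitude
  amp <- gs$amplitude
  nr <- amp$amplitude[amp$label == "non-responsive"]
  rp <- amp$amplitude[amp$label == "responsive"]
  expect_true(all(abs(nr) < 0.2 * min(rp)))
})

test_that("no planted gating at high SNR gives few false positives", {
  cfg <- session_config(n_neurons = 150, n_sounds = 10,
                        presentations_per_sound_per_state = 10,
                        block_duration = 30, seed = 73,
                        gate_prob_nrem = 0, gate_prob_wake = 0)
  s <- generate_session(cfg)
  resp <- extract_responses(s$raster, s$trials)
  tm <- build_templates(resp)
  lab <- label_trials(resp, tm, n_boot = 500, seed = 8)
  expect_lte(mean(lab$label == "non-responsive"), 0.05)
})

test_that("trial shuffling matters only when gains are coordinated", {
  s <- small_session()
  tm <- build_templates(s$resp, n_sounds = 6)
  lab <- label_trials(s$resp, tm, n_boot = 300, seed = 9)
  gs <- gating_summary(lab, s$resp, tm, seed = 10)
  # coordinated gains: the shuffle control removes low-similarity trials, so
  # the observed distribution has a heavier low tail in NREM
  obs_q10 <- quantile(gs$observed_cosines$nrem, 0.1, na.rm = TRUE)
  shf_q10 <- quantile(gs$shuffled_cosines$nrem, 0.1, na.rm = TRUE)
  expect_lt(obs_q10, shf_q10)
})
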