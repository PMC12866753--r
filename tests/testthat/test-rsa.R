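# Brute-force term-by-term evaluation of the noise-corrected similarity
# formulas, written directly from their definition (independent of the
# package's vectorized path).
brute_within <- function(resp, scheme, i, j) {
  avg <- function(ids) {
    sel <- match(ids, resp$trials$trial_id)
    colMeans(resp$responses[sel, , drop = FALSE])
  }
  si_r <- avg(scheme$r[[i]]); si_rp <- avg(scheme$rp[[i]])
  sj_r <- avg(scheme$r[[j]]); sj_rp <- avg(scheme$rp[[j]])
  (cor(si_r, sj_rp) + cor(si_rp, sj_r)) / 2 /
    sqrt(cor(si_r, si_rp) * cor(sj_r, sj_rp))
}

brute_cross <- function(resp, sch2, i, j) {
  avg <- function(ids) {
    sel <- match(ids, resp$trials$trial_id)
    colMeans(resp$responses[sel, , drop = FALSE])
  }
  si_r <- avg(sch2[[1]]$r[[i]]); si_rp <- avg(sch2[[1]]$rp[[i]])
  sj_q <- avg(sch2[[2]]$r[[j]]); sj_qp <- avg(sch2[[2]]$rp[[j]])
  (cor(si_r, sj_q) + cor(si_r, sj_qp) + cor(si_rp, sj_q) +
     cor(si_rp, sj_qp)) / 4 /
    sqrt(cor(si_r, si_rp) * cor(sj_q, sj_qp))
}

test_that("split schemes give disjoint ensembles with equal counts", {
  s <- small_session()
  tr <- s$trials[s$trials$state == "wake", ]
  for (g in c(2, 4)) {
    sch <- split_scheme(tr, g, seed = 5)
    for (si in seq_along(sch[[1]])) {
      ids <- lapply(sch, function(grp) grp[[si]])
      expect_equal(length(unique(lengths(ids))), 1)
      expect_equal(anyDuplicated(unlist(ids)), 0)
    }
  }
  expect_error(split_scheme(tr[tr$trial_id < 3, ], 4), "fewer than")
})

test_that("similarity matches term-by-term brute force exactly", {
  s <- small_session()
  resp <- s$resp
  wake <- resp$trials[resp$trials$state == "wake", ]
  nrem <- resp$trials[resp$trials$state == "nrem", ]
  sch <- split_scheme(wake, 2, seed = 2)
  for (ij in list(c(1, 1), c(2, 5), c(4, 3))) {
    expect_identical(
      noise_corrected_similarity(resp, sch, ij[1], ij[2], "within"),
      brute_within(resp, sch, ij[1], ij[2]))
  }
  sch2 <- list(split_scheme(wake, 2, seed = 2),
               split_scheme(nrem, 2, seed = 3))
  for (ij in list(c(1, 1), c(3, 3), c(2, 6))) {
    expect_identical(
      noise_corrected_similarity(resp, sch2, ij[1], ij[2], "cross"),
      brute_cross(resp, sch2, ij[1], ij[2]))
  }
  # the vectorized matrix path agrees with the per-pair definition
  m <- sleepgeom:::rsa_matrix_once(resp, sch, "within")
  for (i in c(1, 3)) for (j in c(2, 7))
    expect_equal(m[i, j], brute_within(resp, sch, i, j))
  mc <- sleepgeom:::rsa_matrix_once(resp, sch2, "cross")
  for (i in c(1, 4)) for (j in c(1, 5))
    expect_equal(mc[i, j], brute_cross(resp, sch2, i, j))
})

test_that("degenerate pattern geometries give the forced limits", {
  # identical noise-free patterns, i = j -> exactly 1
  pat <- runif(30)
  resp <- manual_responses(matrix(rep(pat, 8), 8, byrow = TRUE),
                           sound_id = rep(1, 8))
  sch <- split_scheme(resp$trials, 2, seed = 1)
  expect_equal(noise_corrected_similarity(resp, sch, 1, 1, "within"), 1)
  # independent (expected-orthogonal after centering) mean patterns -> near 0
  set.seed(31)
  nn <- 300
  p1 <- abs(rnorm(nn, 1, 1))
  p2 <- abs(rnorm(nn, 1, 1))
  resp2 <- manual_responses(
    rbind(matrix(rep(p1, 20), 20, byrow = TRUE),
          matrix(rep(p2, 20), 20, byrow = TRUE)) +
      matrix(rnorm(40 * nn, sd = 0.3), 40),
    sound_id = rep(1:2, each = 20))
  sch2 <- split_scheme(resp2$trials, 2, seed = 1)
  expect_lt(abs(noise_corrected_similarity(resp2, sch2, 1, 2, "within")),
            0.15)
})

test_that("non-positive reliability is flagged, never clipped", {
  set.seed(41)
  resp <- manual_responses(matrix(rnorm(400), 20), sound_id = rep(1:2, 10))
  # pure noise: some split gives non-positive reliability eventually
  flagged <- FALSE
  for (seed in 1:25) {
    sch <- split_scheme(resp$trials, 2, seed = seed)
    v <- noise_corrected_similarity(resp, sch, 1, 2, "within")
    if (is.na(v)) {
      flagged <- TRUE
      expect_identical(attr(v, "reason"), "non-positive reliability")
      break
    }
  }
  expect_true(flagged)
})

test_that("similarity is invariant to a per-state multiplicative gain", {
  s <- small_session()
  resp <- s$resp
  scaled <- resp
  nrem_rows <- resp$trials$state == "nrem"
  scaled$responses[nrem_rows, ] <- 0.31 * resp$responses[nrem_rows, ]
  sch2 <- list(split_scheme(resp$trials[resp$trials$state == "wake", ], 2,
                            seed = 4),
               split_scheme(resp$trials[nrem_rows, ], 2, seed = 5))
  for (i in 1:3)
    expect_equal(noise_corrected_similarity(resp, sch2, i, i, "cross"),
                 noise_corrected_similarity(scaled, sch2, i, i, "cross"))
})

test_that("averaged within-state matrix is symmetric up to split noise", {
  s <- small_session()
  r <- rsa_summary(s$resp, "wake", n_splits = 8, seed = 6)
  expect_lt(max(abs(r$similarity - t(r$similarity)), na.rm = TRUE), 0.2)
  expect_equal(mean(diag(r$similarity), na.rm = TRUE), 1)
})

test_that("cross-state summary: high diagonal, centered chance, unit ceiling", {
  s <- small_session()
  r <- rsa_summary(s$resp, c("wake", "nrem"), n_splits = 6, seed = 8)
  expect_gt(r$diag_mean, 0.9)  # same tuning in both states
  expect_lt(abs(mean(r$chance)), 0.15)
  expect_lt(abs(mean(r$ceiling) - 1), 0.05)
})
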