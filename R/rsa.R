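# Noise-ceiling-corrected representational similarity analysis.
#
# A raw Pearson correlation between trial-averaged population vectors
# under-estimates pattern similarity because of trial-to-trial noise. Split
# each sound's presentations into independent ensembles, and normalize the
# cross-ensemble correlation by the geometric mean of the split-half
# reliabilities, so that identical underlying representations score 1 in
# expectation:
#
#   within:  [rho(<Si>r,<Sj>r') + rho(<Si>r',<Sj>r)] /
#            (2 * sqrt(rho(<Si>r,<Si>r') * rho(<Sj>r,<Sj>r')))
#   cross:   mean of the four r/r' x q/q' correlations /
#            sqrt(rho(<Si>r,<Si>r') * rho(<Sj>q,<Sj>q'))

#' Random split scheme for RSA ensembles
#'
#' Splits each sound's trial ids into disjoint ensembles with exactly equal
#' per-sound counts (surplus trials are dropped at random so counts are equal,
#' never off by one).
#'
#' @param trials trial table subset (one state).
#' @param n_groups 2 for within-state (r, r'), 4 for the ceiling split
#'   (r, r', q, q').
#' @param seed integer seed.
#' @return list (per group) of lists (per sound) of trial ids.
#' @export
split_scheme <- function(trials, n_groups = 2, seed = 1) {
  set.seed(seed)
  sounds <- sort(unique(trials$sound_id))
  groups <- replicate(n_groups, vector("list", length(sounds)),
                      simplify = FALSE)
  for (si in seq_along(sounds)) {
    ids <- trials$trial_id[trials$sound_id == sounds[si]]
    per <- length(ids) %/% n_groups
    if (per < 1)
      stop("sound ", sounds[si], " has fewer than ", n_groups,
           " presentations")
    ids <- sample(ids, per * n_groups)
    for (g in seq_len(n_groups))
      groups[[g]][[si]] <- ids[seq((g - 1) * per + 1, g * per)]
  }
  names(groups) <- c("r", "rp", "q", "qp")[seq_len(n_groups)]
  attr(groups, "sounds") <- sounds
  groups
}

# trial-averaged population vector for one sound in one ensemble
ensemble_mean <- function(resp, ids) {
  sel <- match(ids, resp$trials$trial_id)
  colMeans(resp$responses[sel, , drop = FALSE])
}

#' Noise-corrected similarity of two sound representations
#'
#' @param resp `sg_responses` (or, for `mode = "cross"`, responses holding
#'   both states' trials).
#' @param scheme for `mode = "within"` a 2-group [split_scheme()]; for
#'   `"cross"` a list `list(wake = <2-group scheme>, other = <2-group
#'   scheme>)` built on the two states' trials.
#' @param i,j sound indices into the scheme's sound list.
#' @param mode `"within"` or `"cross"`.
#' @return scalar similarity; `NA` (flagged via attribute `reason`) when a
#'   split-half reliability is not strictly positive.
#' @export
noise_corrected_similarity <- function(resp, scheme, i, j,
                                       mode = c("within", "cross")) {
  mode <- match.arg(mode)
  if (mode == "within") {
    si_r <- ensemble_mean(resp, scheme$r[[i]])
    si_rp <- ensemble_mean(resp, scheme$rp[[i]])
    sj_r <- ensemble_mean(resp, scheme$r[[j]])
    sj_rp <- ensemble_mean(resp, scheme$rp[[j]])
    rel_i <- cor(si_r, si_rp)
    rel_j <- cor(sj_r, sj_rp)
    if (!isTRUE(rel_i > 0) || !isTRUE(rel_j > 0))
      return(structure(NA_real_, reason = "non-positive reliability"))
    num <- (cor(si_r, sj_rp) + cor(si_rp, sj_r)) / 2
    num / sqrt(rel_i * rel_j)
  } else {
    a <- scheme[[1]]; b <- scheme[[2]]
    si_r <- ensemble_mean(resp, a$r[[i]])
    si_rp <- ensemble_mean(resp, a$rp[[i]])
    sj_q <- ensemble_mean(resp, b$r[[j]])
    sj_qp <- ensemble_mean(resp, b$rp[[j]])
    rel_i <- cor(si_r, si_rp)
    rel_j <- cor(sj_q, sj_qp)
    if (!isTRUE(rel_i > 0) || !isTRUE(rel_j > 0))
      return(structure(NA_real_, reason = "non-positive reliability"))
    num <- (cor(si_r, sj_q) + cor(si_r, sj_qp) +
              cor(si_rp, sj_q) + cor(si_rp, sj_qp)) / 4
    num / sqrt(rel_i * rel_j)
  }
}

# neurons x sounds matrix of ensemble means for one group of a scheme
ensemble_mean_matrix <- function(resp, group) {
  vapply(group, function(ids) ensemble_mean(resp, ids),
         numeric(ncol(resp$responses)))
}

# vectorized full-matrix evaluation; agrees entry-by-entry with
# noise_corrected_similarity (asserted in the test suite)
rsa_matrix_once <- function(resp, scheme, mode) {
  if (mode == "within") {
    sounds <- attr(scheme, "sounds")
    mr <- ensemble_mean_matrix(resp, scheme$r)
    mrp <- ensemble_mean_matrix(resp, scheme$rp)
    num <- (cor(mr, mrp) + cor(mrp, mr)) / 2
    rel_i <- rel_j <- diag(cor(mr, mrp))
  } else {
    sounds <- attr(scheme[[1]], "sounds")
    mr <- ensemble_mean_matrix(resp, scheme[[1]]$r)
    mrp <- ensemble_mean_matrix(resp, scheme[[1]]$rp)
    mq <- ensemble_mean_matrix(resp, scheme[[2]]$r)
    mqp <- ensemble_mean_matrix(resp, scheme[[2]]$rp)
    num <- (cor(mr, mq) + cor(mr, mqp) + cor(mrp, mq) + cor(mrp, mqp)) / 4
    rel_i <- diag(cor(mr, mrp))
    rel_j <- diag(cor(mq, mqp))
  }
  bad_i <- !(rel_i > 0)
  bad_j <- !(rel_j > 0)
  rel_i[bad_i] <- NA
  rel_j[bad_j] <- NA
  vals <- num / sqrt(outer(rel_i, rel_j))
  dimnames(vals) <- list(sounds, sounds)
  vals
}

#' RSA summary: similarity matrix, chance and ceiling distributions
#'
#' Builds the sounds x sounds noise-corrected similarity matrix averaged over
#' `n_splits` random split schemes. For `mode = "cross"`, the diagonal chance
#' distribution comes from mismatching sound identity between the two states,
#' and the ceiling distribution from splitting the first state's data into 4
#' non-overlapping ensembles (r, r', q, q') and treating (r, r') vs (q, q') as
#' two pseudo-states (centered near 1 when representations are identical).
#'
#' @param resp `sg_responses` covering all needed trials.
#' @param states length-1 (within) or length-2 (cross) character vector of
#'   state labels.
#' @param n_splits number of random schemes averaged (default 20).
#' @param seed integer seed.
#' @param ceiling compute the 4-way ceiling distribution (cross mode; needs at
#'   least 4 presentations per sound in the first state).
#' @return list: `similarity` (matrix), `diag_mean`, `diag_sd`, `chance`
#'   (vector or NULL), `ceiling` (per-sound vector or NULL), `qc` (count of
#'   unreliable entries).
#' @export
rsa_summary <- function(resp, states, n_splits = 20, seed = 1,
                        ceiling = length(states) == 2) {
  mode <- if (length(states) == 1) "within" else "cross"
  trials <- resp$trials
  acc <- NULL
  chance <- NULL
  ceil <- NULL
  for (s in seq_len(n_splits)) {
    if (mode == "within") {
      scheme <- split_scheme(trials[trials$state == states[1], ], 2,
                             seed = seed + 1000 * s)
    } else {
      scheme <- list(
        split_scheme(trials[trials$state == states[1], ], 2,
                     seed = seed + 1000 * s),
        split_scheme(trials[trials$state == states[2], ], 2,
                     seed = seed + 1000 * s + 1))
    }
    vals <- rsa_matrix_once(resp, scheme, mode)
    acc <- if (is.null(acc)) vals else acc + vals
    if (mode == "cross") {
      m <- nrow(vals)
      set.seed(seed + 7000 * s)
      perm <- derangement(m)
      chance <- c(chance, vals[cbind(seq_len(m), perm)])
    }
  }
  sim <- acc / n_splits
  if (ceiling) {
    st1 <- trials[trials$state == states[1], ]
    ceil <- tryCatch(
      rsa_ceiling(resp, st1, n_splits = n_splits, seed = seed + 555),
      error = function(e) NULL)
  }
  dvals <- diag(sim)
  list(similarity = sim, diag_mean = mean(dvals, na.rm = TRUE),
       diag_sd = sd(dvals, na.rm = TRUE), chance = chance, ceiling = ceil,
       qc = sum(is.na(sim)))
}

# permutation with no fixed point (identity mismatch for the chance level)
derangement <- function(m) {
  repeat {
    p <- sample.int(m)
    if (!any(p == seq_len(m))) return(p)
  }
}

#' Noise-ceiling distribution from a 4-way within-state split
#'
#' Splits one state's presentations into 4 non-overlapping ensembles and
#' evaluates the cross-state formula with (r, r') and (q, q') as the two
#' pseudo-states; since both halves share the underlying representation the
#' per-sound values should center near 1.
#'
#' @param resp `sg_responses`.
#' @param trials trial table rows of the chosen state.
#' @param n_splits random 4-way schemes to average per sound.
#' @param seed integer seed.
#' @return per-sound numeric vector, averaged over the splits where both
#'   pseudo-state reliabilities are strictly positive (other splits are
#'   flagged-undefined and excluded; valid counts in attribute `n_valid`).
#' @export
rsa_ceiling <- function(resp, trials, n_splits = 20, seed = 1) {
  acc <- n_valid <- NULL
  for (s in seq_len(n_splits)) {
    g4 <- split_scheme(trials, 4, seed = seed + 31 * s)
    mr <- ensemble_mean_matrix(resp, g4$r)
    mrp <- ensemble_mean_matrix(resp, g4$rp)
    mq <- ensemble_mean_matrix(resp, g4$q)
    mqp <- ensemble_mean_matrix(resp, g4$qp)
    num <- (diag(cor(mr, mq)) + diag(cor(mr, mqp)) +
              diag(cor(mrp, mq)) + diag(cor(mrp, mqp))) / 4
    rel_i <- diag(cor(mr, mrp))
    rel_j <- diag(cor(mq, mqp))
    ok_rel <- rel_i > 0 & rel_j > 0
    vals <- num / suppressWarnings(sqrt(rel_i * rel_j))
    vals[!ok_rel] <- NA  # flagged-undefined split
    ok <- !is.na(vals)
    if (is.null(acc)) {
      acc <- ifelse(ok, vals, 0)
      n_valid <- as.integer(ok)
    } else {
      acc <- acc + ifelse(ok, vals, 0)
      n_valid <- n_valid + ok
    }
  }
  out <- ifelse(n_valid > 0, acc / n_valid, NA_real_)
  attr(out, "n_valid") <- n_valid
  out
}
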