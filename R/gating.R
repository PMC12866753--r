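# Bootstrap detection of "non-responsive" population events: single trials
# whose response pattern is statistically indistinguishable from orthogonal to
# the sound's template response.

# mean baseline-subtracted population rate per trial
trial_intensity <- function(resp) {
  rowMeans(resp$responses - resp$baselines)
}

#' Template response patterns for the most responsive sounds
#'
#' Sounds are ranked by their mean baseline-subtracted population response
#' (over the requested states) and the top `n_sounds` kept. For each kept
#' sound, trials are ranked by population response intensity and the strongest
#' `top_frac` fraction (ceiling; ties broken by trial id) are averaged into a
#' template vector.
#'
#' @param resp `sg_responses`.
#' @param top_frac fraction of strongest trials averaged (default 0.3).
#' @param n_sounds number of sounds retained (default 10).
#' @param states states whose trials define sound ranking and templates
#'   (default wake + NREM).
#' @return named list (sound id) of template vectors (neurons), with
#'   attribute `sound_rank`.
#' @export
build_templates <- function(resp, top_frac = 0.3, n_sounds = 10,
                            states = c("wake", "nrem")) {
  trials <- resp$trials
  sel <- trials$state %in% states
  intensity <- trial_intensity(resp)
  by_sound <- tapply(intensity[sel], trials$sound_id[sel], mean)
  ranked <- as.integer(names(sort(by_sound, decreasing = TRUE)))
  keep <- head(ranked, n_sounds)
  delta <- resp$responses - resp$baselines
  templates <- lapply(keep, function(s) {
    idx <- which(trials$sound_id == s & sel)
    n_top <- ceiling(top_frac * length(idx))
    if (n_top < 1) stop("too few trials for sound ", s)
    ord <- idx[order(-intensity[idx], trials$trial_id[idx])]
    colMeans(delta[ord[seq_len(n_top)], , drop = FALSE])
  })
  names(templates) <- keep
  attr(templates, "sound_rank") <- ranked
  templates
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Bootstrap labeling of responsive vs non-responsive trials
#'
#' For every trial of a templated sound, the cosine similarity between the
#' baseline-subtracted trial vector and the sound's template is computed, and
#' its sampling variability estimated by resampling neurons with replacement
#' `n_boot` times. A trial is `non-responsive` when 0 lies inside the
#' `[pct[1], pct[2]]` percentile interval of the bootstrap distribution
#' (zero-norm trial vectors are non-responsive by convention and counted in
#' the `zero_vectors` attribute).
#'
#' @param resp `sg_responses`.
#' @param templates output of [build_templates()].
#' @param n_boot bootstrap resamples (default 1000).
#' @param pct percentile bounds (default `c(5, 95)`).
#' @param seed integer seed.
#' @param states trials of these states are labeled (default wake + NREM).
#' @return data.frame: trial_id, sound_id, state, cosine, lo, hi, label.
#' @export
label_trials <- function(resp, templates, n_boot = 1000, pct = c(5, 95),
                         seed = 1, states = c("wake", "nrem")) {
  trials <- resp$trials
  delta <- resp$responses - resp$baselines
  keep <- which(trials$sound_id %in% as.integer(names(templates)) &
                  trials$state %in% states)
  set.seed(seed)
  n <- ncol(delta)
  zero_vectors <- 0L
  rows <- lapply(keep, function(k) {
    tmpl <- templates[[as.character(trials$sound_id[k])]]
    if (all(tmpl == 0)) stop("zero template for sound ", trials$sound_id[k])
    v <- delta[k, ]
    cs <- cosine(v, tmpl)
    if (is.na(cs)) {
      zero_vectors <<- zero_vectors + 1L
      return(data.frame(trial_id = trials$trial_id[k],
                        sound_id = trials$sound_id[k],
                        state = trials$state[k], cosine = NA_real_,
                        lo = NA_real_, hi = NA_real_,
                        label = "non-responsive"))
    }
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    vb <- matrix(v[idx], n_boot, n)
    tb <- matrix(tmpl[idx], n_boot, n)
    boot <- rowSums(vb * tb) / (sqrt(rowSums(vb^2)) * sqrt(rowSums(tb^2)))
    qs <- quantile(boot, pct / 100, na.rm = TRUE, names = FALSE)
    data.frame(trial_id = trials$trial_id[k], sound_id = trials$sound_id[k],
               state = trials$state[k], cosine = cs, lo = qs[1], hi = qs[2],
               label = if (qs[1] <= 0 && 0 <= qs[2]) "non-responsive" else
                 "responsive")
  })
  out <- do.call(rbind, rows)
  attr(out, "zero_vectors") <- zero_vectors
  out
}

#' Gating summary statistics
#'
#' @param labels output of [label_trials()].
#' @param resp `sg_responses`.
#' @param templates templates used for labeling (needed for the shuffle
#'   control).
#' @param seed integer seed for the neuron-wise trial shuffle control.
#' @return list: `fraction_nonresponsive` (named by state), `amplitude`
#'   (data.frame state/label/mean baseline-subtracted population amplitude),
#'   `observed_cosines`, `shuffled_cosines` (per state lists, for cumulative
#'   distributions).
#' @export
gating_summary <- function(labels, resp, templates, seed = 1) {
  states <- unique(labels$state)
  frac <- vapply(states, function(st)
    mean(labels$label[labels$state == st] == "non-responsive"), numeric(1))
  names(frac) <- states
  intensity <- trial_intensity(resp)
  idx <- match(labels$trial_id, resp$trials$trial_id)
  amp <- aggregate(list(amplitude = intensity[idx]),
                   by = list(state = labels$state, label = labels$label),
                   FUN = mean)
  # shuffle control: permute each neuron's responses independently across the
  # trials of a sound x state cell, destroying cross-neuron coordination
  delta <- resp$responses - resp$baselines
  set.seed(seed)
  observed <- shuffled <- list()
  for (st in states) {
    obs <- labels$cosine[labels$state == st]
    shf <- c()
    for (s in as.integer(names(templates))) {
      rows <- idx[labels$state == st & labels$sound_id == s]
      m <- delta[rows, , drop = FALSE]
      if (nrow(m) < 2) next
      msh <- apply(m, 2, function(col) col[sample.int(length(col))])
      tmpl <- templates[[as.character(s)]]
      shf <- c(shf, apply(msh, 1, cosine, b = tmpl))
    }
    observed[[st]] <- obs
    shuffled[[st]] <- shf
  }
  list(fraction_nonresponsive = frac, amplitude = amp,
       observed_cosines = observed, shuffled_cosines = shuffled)
}
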