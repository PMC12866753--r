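# Cross-validated PCA dimensionality with a circular-shift null, and the
# spontaneous/evoked subspace inclusion index.

# circularly shift each column (neuron) of a frames x neurons matrix by an
# independent uniform offset in [1, T-1]
circular_shift_cols <- function(x) {
  n <- nrow(x)
  shifts <- sample.int(n - 1L, ncol(x), replace = TRUE)
  for (j in seq_len(ncol(x))) {
    s <- shifts[j]
    x[, j] <- x[c((n - s + 1L):n, 1L:(n - s)), j]
  }
  x
}

# total variance (sum of column variances) of the projection of centered xc
# onto each column of v, as a fraction of the total variance of xc
component_var_ratio <- function(xc, v, total) {
  p <- xc %*% v
  colSums(p^2) / (nrow(xc) - 1) / total
}

#' Cross-validated PCA scree plot with a circular-shift null
#'
#' The frame series is split into `k_folds` contiguous blocks; per fold,
#' principal components are estimated on the train blocks (train-mean
#' centering) and the held-out block is projected onto them to measure the
#' variance-ratio each component captures out of sample. The chance curve is
#' the 95th percentile of the same statistic with the test block circularly
#' shifted in time independently per neuron (`n_shuffles` draws per fold).
#' Dimensionality is the length of the initial run of components whose
#' cross-validated variance exceeds chance.
#'
#' @param activity frames x neurons matrix, z-scored over the whole recording
#'   (see [zscore_frames()]).
#' @param k_folds contiguous cross-validation blocks (default 5).
#' @param n_shuffles circular shuffles per fold for the null (default 20).
#' @param seed integer seed (drives the shuffles).
#' @param n_components components to evaluate (default `min(dim) - 1`).
#' @return list: `cv_variance_ratio`, `chance_95` (per component),
#'   `dimensionality`.
#' @export
cv_scree <- function(activity, k_folds = 5, n_shuffles = 20, seed = 1,
                     n_components = NULL) {
  n_frames <- nrow(activity)
  if (k_folds > n_frames) stop("k_folds exceeds number of frames")
  if (n_frames < 10 * k_folds) stop("need at least 10 frames per fold")
  set.seed(seed)
  if (is.null(n_components))
    n_components <- min(n_frames - max(1, n_frames %/% k_folds) - 1,
                        ncol(activity))
  bounds <- floor(seq(0, n_frames, length.out = k_folds + 1))
  cv <- matrix(0, k_folds, n_components)
  null_vals <- array(0, c(k_folds, n_shuffles, n_components))
  for (f in seq_len(k_folds)) {
    test_idx <- (bounds[f] + 1):bounds[f + 1]
    train <- activity[-test_idx, , drop = FALSE]
    test <- activity[test_idx, , drop = FALSE]
    mu <- colMeans(train)
    trainc <- sweep(train, 2, mu)
    sv <- svd(trainc, nu = 0, nv = n_components)
    v <- sv$v
    testc <- sweep(test, 2, mu)
    total <- sum(colSums(testc^2)) / (nrow(testc) - 1)
    cv[f, ] <- component_var_ratio(testc, v, total)
    for (s in seq_len(n_shuffles)) {
      shuf <- circular_shift_cols(testc)
      total_s <- sum(colSums(shuf^2)) / (nrow(shuf) - 1)
      null_vals[f, s, ] <- component_var_ratio(shuf, v, total_s)
    }
  }
  cv_mean <- colMeans(cv)
  chance <- apply(null_vals, 3, quantile, probs = 0.95)
  above <- cv_mean > chance
  dim_est <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  list(cv_variance_ratio = cv_mean, chance_95 = chance,
       dimensionality = as.integer(dim_est))
}

# first n principal components (neurons x n) of a frames x neurons matrix
pca_components <- function(x, n) {
  xc <- sweep(x, 2, colMeans(x))
  svd(xc, nu = 0, nv = n)$v
}

# Var(X V V^T) / Var(X Vsrc Vsrc^T), both as total projected variance of the
# column-centered source
proj_var_ratio <- function(x, v_ref, v_src) {
  xc <- sweep(x, 2, colMeans(x))
  num <- sum((xc %*% v_ref)^2)
  den <- sum((xc %*% v_src)^2)
  num / den
}

#' Inclusion of evoked activity in the spontaneous subspace
#'
#' Spontaneous activity is split into 10 contiguous blocks; odd blocks form
#' the reference set whose cross-validated dimensionality `n` defines the
#' reference subspace `V_ref` (first `n` PCs). For a source matrix,
#' `%Var = Var(X V_ref V_ref^T) / Var(X V_src V_src^T)` with `V_src` the
#' source's own first `n` PCs. `var_max` uses the even spontaneous blocks,
#' `var_projected` the evoked activity, `var_chance` the evoked activity
#' circularly shifted per neuron. The index is
#' `(var_projected - var_chance) / (var_max - var_chance)`.
#'
#' @param spont,evoked frames x neurons matrices over the same neurons,
#'   z-scored over the whole recording.
#' @param seed integer seed (dimensionality null + chance shifts).
#' @param n_chance number of circular-shift draws averaged for the chance
#'   level (default 10).
#' @param n_ref optional override of the reference dimensionality.
#' @return list: `index`, `var_max`, `var_projected`, `var_chance`, `n_ref`.
#' @export
inclusion_index <- function(spont, evoked, seed = 1, n_chance = 10,
                            n_ref = NULL) {
  if (ncol(spont) != ncol(evoked)) stop("neuron sets must match")
  n_frames <- nrow(spont)
  bounds <- floor(seq(0, n_frames, length.out = 11))
  blocks <- lapply(seq_len(10), function(b) (bounds[b] + 1):bounds[b + 1])
  odd <- do.call(c, blocks[seq(1, 9, by = 2)])
  even <- do.call(c, blocks[seq(2, 10, by = 2)])
  ref <- spont[odd, , drop = FALSE]
  if (is.null(n_ref)) {
    scree <- cv_scree(ref, seed = seed)
    n_ref <- scree$dimensionality
  }
  if (n_ref < 1) stop("degenerate reference subspace (dimensionality 0)")
  v_ref <- pca_components(ref, n_ref)
  var_of <- function(x) {
    v_src <- pca_components(x, n_ref)
    proj_var_ratio(x, v_ref, v_src)
  }
  var_max <- var_of(spont[even, , drop = FALSE])
  var_projected <- var_of(evoked)
  set.seed(seed + 1)
  var_chance <- mean(vapply(seq_len(n_chance), function(s)
    var_of(circular_shift_cols(evoked)), numeric(1)))
  list(index = (var_projected - var_chance) / (var_max - var_chance),
       var_max = var_max, var_projected = var_projected,
       var_chance = var_chance, n_ref = n_ref)
}

#' Frame selections for spontaneous and evoked activity
#'
#' Helper mapping a generated session to the two activity matrices the
#' subspace analyses consume: spontaneous frames (silence blocks) and evoked
#' frames (response windows of sound presentations), restricted to one state.
#'
#' @param session output of [generate_session()].
#' @param state `"wake"` or `"nrem"`.
#' @param zscore z-score over the whole recording first (default TRUE).
#' @return list of matrices `spont`, `evoked` (frames x neurons).
#' @export
session_activity_matrices <- function(session, state, zscore = TRUE) {
  cfg <- session$config
  x <- t(session$raster$counts)
  if (zscore) x <- zscore_frames(x)
  n_frames <- nrow(x)
  frame_t <- (seq_len(n_frames) - 1) / cfg$frame_rate
  blocks <- session$truth$blocks
  st_ok <- session$truth$state_sequence == state
  spont_sel <- rep(FALSE, n_frames)
  for (i in which(blocks$type == "silence" & blocks$state == state)) {
    sel <- frame_t >= blocks$start_s[i] &
      frame_t < blocks$start_s[i] + blocks$duration[i]
    spont_sel <- spont_sel | sel
  }
  spont_sel <- spont_sel & st_ok
  evoked_sel <- rep(FALSE, n_frames)
  tr <- session$trials[session$trials$state == state, ]
  for (k in seq_len(nrow(tr)))
    evoked_sel[response_frames(cfg, tr$onset_s[k], n_frames)] <- TRUE
  list(spont = x[spont_sel, , drop = FALSE],
       evoked = x[evoked_sel, , drop = FALSE])
}
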