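# Balanced, stratified cross-validated linear decoding of sound identity.

#' Balanced stratified fold assignment
#'
#' Downsamples (without replacement) so every sound contributes the same
#' number of presentations, optionally equalizing per-sound counts with a
#' second state first, then deals each sound's trials across `k` folds so per-
#' fold per-sound counts are equal.
#'
#' @param resp `sg_responses`.
#' @param state state label to decode in.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param equalize_with optional second state label; per-sound counts are
#'   capped at the poorer state's count.
#' @return data.frame `trial_id`, `sound_id`, `fold`; sounds with fewer than
#'   `k` presentations are dropped and reported in attribute `dropped_sounds`.
#' @export
prepare_balanced_folds <- function(resp, state, k = 5, seed = 1,
                                   equalize_with = NULL) {
  trials <- resp$trials
  tr <- trials[trials$state == state, ]
  counts <- table(tr$sound_id)
  cap <- min(counts)
  if (!is.null(equalize_with)) {
    other <- table(trials$sound_id[trials$state == equalize_with])
    if (length(other)) cap <- min(cap, min(other))
  }
  dropped <- as.integer(names(counts)[counts < k])
  if (length(dropped))
    message("dropping ", length(dropped), " sound(s) with < ", k,
            " presentations")
  sounds <- as.integer(names(counts)[counts >= k])
  if (cap < k) stop("fewer than k presentations per sound after equalization")
  per <- (cap %/% k) * k  # equal per-fold counts
  set.seed(seed)
  out <- do.call(rbind, lapply(sounds, function(s) {
    ids <- sample(tr$trial_id[tr$sound_id == s], per)
    data.frame(trial_id = ids, sound_id = s,
               fold = rep(seq_len(k), each = per %/% k))
  }))
  attr(out, "dropped_sounds") <- dropped
  attr(out, "n_per_class") <- per
  out
}

#' Cross-validated linear decoding of sound identity
#'
#' Trains a ridge-regularized multinomial logistic regression (a linear
#' classifier) on k-1 folds and evaluates on the held-out fold; reports the
#' weighted F1 score pooled over test folds and the accumulated confusion
#' matrix.
#'
#' @param folds fold assignment from [prepare_balanced_folds()].
#' @param resp `sg_responses`.
#' @param lambda ridge penalty (default 0.01).
#' @param permute_labels permute sound labels before training (chance-level
#'   control; seeded by `seed`).
#' @param seed integer seed for the permutation control.
#' @return `sg_decoding` list: `accuracy` (weighted F1), `confusion`
#'   (sounds x sounds counts, rows = true), `per_fold`, `n_per_class`, `seed`.
#' @export
decode <- function(folds, resp, lambda = 0.01, permute_labels = FALSE,
                   seed = 1) {
  sounds <- sort(unique(folds$sound_id))
  if (length(sounds) < 2) stop("need at least 2 classes")
  y <- factor(folds$sound_id, levels = sounds)
  if (permute_labels) {
    set.seed(seed)
    y <- y[sample.int(length(y))]
  }
  x <- resp$responses[match(folds$trial_id, resp$trials$trial_id), ,
                      drop = FALSE]
  if (all(apply(x, 2, sd) == 0)) stop("degenerate constant features")
  k <- max(folds$fold)
  confusion <- matrix(0L, length(sounds), length(sounds),
                      dimnames = list(sounds, sounds))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds$fold == f
    # decreasing path down to the requested penalty: glmnet's coordinate
    # descent needs the warm-started path to converge for multinomial ridge.
    # glmnet warns whenever a class has < 8 training rows, which is routine
    # for small balanced folds; that specific warning is muffled.
    fit <- withCallingHandlers(
      glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                     family = "multinomial", alpha = 0,
                     lambda = exp(seq(log(50), log(lambda),
                                      length.out = 25)),
                     standardize = TRUE, maxit = 1e5),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    pred <- predict(fit, x[test, , drop = FALSE], s = lambda,
                    type = "class")
    cm <- table(factor(y[test], levels = sounds),
                factor(pred, levels = sounds))
    confusion <- confusion + as.matrix(cm)
    per_fold[f] <- weighted_f1(as.matrix(cm))
  }
  structure(list(accuracy = weighted_f1(confusion), confusion = confusion,
                 per_fold = per_fold,
                 n_per_class = attr(folds, "n_per_class"), seed = seed),
            class = "sg_decoding")
}

#' Weighted F1 score from a confusion matrix
#'
#' Per-class F1 scores averaged with weights equal to the true (row) support.
#' Classes with no predicted or true positives get F1 = 0.
#'
#' @param confusion square count matrix, rows = true classes.
#' @return scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(confusion) {
  tp <- diag(confusion)
  support <- rowSums(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  sum(f1 * support) / sum(support)
}

#' @export
print.sg_decoding <- function(x, ...) {
  cat(sprintf("<sg_decoding> weighted F1 = %.3f over %d classes (%d/class)\n",
              x$accuracy, nrow(x$confusion), x$n_per_class))
  invisible(x)
}
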