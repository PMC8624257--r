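# MLP posture classification.
#
# A single-hidden-layer perceptron (8 x dims inputs, 17 hidden nodes by
# default, one softmax output per posture) trained by quasi-Newton
# backpropagation via nnet, with weight decay as the regularizer. Inputs
# are standardized per column using training-set statistics only. Models
# are subject-specific: the sessions-of-training protocol trains and tests
# within each subject.

fm_xy <- function(fm, levels = NULL) {
  x <- as.matrix(fm[attr(fm, "value_cols")])
  y <- factor(fm$posture_id, levels = levels %||% sort(unique(fm$posture_id)))
  list(x = x, y = y)
}

#' Train the MLP classifier
#'
#' @param x numeric feature matrix (rows = windows).
#' @param y factor of posture labels; every level must occur in `y`.
#' @param n_hidden hidden-layer nodes (default 17).
#' @param seed integer seed; identical data and seed give identical
#'   weights.
#' @param maxit,decay optimizer iterations and weight-decay penalty.
#' @param n_restarts random restarts; the fit with the lowest final
#'   objective is kept (seeded, so still deterministic).
#' @return a `semg_mlp` with the fitted network, the training-column
#'   statistics used for standardization, and training diagnostics
#'   (`value`: final penalized objective; `convergence`).
#' @export
train_mlp <- function(x, y, n_hidden = 17, seed = 1L, maxit = 150,
                      decay = 1e-3, n_restarts = 1L) {
  x <- as.matrix(x)
  y <- droplevels_check(y)
  if (nrow(x) < 10 * nlevels(y))
    stopf("need at least 10 rows per class signature (10 x %d = %d), got %d",
          nlevels(y), 10 * nlevels(y), nrow(x))
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, center = mu, scale = sdv)
  target <- nnet::class.ind(y)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, r),
      nnet::nnet(xs, target, size = n_hidden, softmax = TRUE,
                 maxit = maxit, decay = decay, trace = FALSE,
                 MaxNWts = 20000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(
    list(net = best, mu = mu, sdv = sdv, levels = levels(y),
         n_hidden = n_hidden, seed = seed,
         value = best$value, convergence = best$convergence),
    class = "semg_mlp")
}

# Draw n_repeats training-session subsets of size k: all distinct subsets
# when the subset space is small enough, otherwise distinct sampled subsets
# (falling back to duplicates only if the rejection budget is exhausted).
draw_session_subsets <- function(sessions, k, n_repeats, seed) {
  n_total <- choose(length(sessions), k)
  if (n_total <= n_repeats) {
    cmb <- combn(sessions, k)
    return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  with_seed(seed, {
    out <- list()
    keys <- character(0)
    tries <- 0L
    while (length(out) < n_repeats && tries < 50L * n_repeats) {
      tries <- tries + 1L
      s <- sort(sample(sessions, k))
      key <- paste(s, collapse = "+")
      if (key %in% keys && n_total > length(out)) next
      keys <- c(keys, key)
      out[[length(out) + 1L]] <- s
    }
    out
  })
}

droplevels_check <- function(y) {
  y <- as.factor(y)
  absent <- setdiff(levels(y), as.character(unique(y)))
  if (length(absent))
    stopf("class(es) absent from training data: %s",
          paste(absent, collapse = ", "))
  y
}

#' @export
predict.semg_mlp <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  xs <- scale(as.matrix(newdata), center = object$mu, scale = object$sdv)
  p <- predict(object$net, xs)
  if (type == "prob") return(p)
  factor(object$levels[max.col(p, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.semg_mlp <- function(x, ...) {
  cat(sprintf("<semg_mlp> %d-%d-%d, objective %.4g\n",
              length(x$mu), x$n_hidden, length(x$levels), x$value))
  invisible(x)
}

#' Confusion matrix of true vs predicted postures
#'
#' @param true,pred factors on the same levels (rows = true,
#'   columns = predicted).
#' @param levels optional explicit level set.
#' @return integer posture x posture matrix.
#' @export
confusion_matrix <- function(true, pred, levels = NULL) {
  levels <- levels %||% sort(unique(c(as.character(true), as.character(pred))))
  unclass(table(factor(true, levels), factor(pred, levels)))
}

#' Accuracy of a confusion matrix, in percent
#'
#' @param cm square count matrix.
#' @return `100 * trace / total`.
#' @export
confusion_accuracy <- function(cm) 100 * sum(diag(cm)) / sum(cm)

#' Evaluate a feature matrix under the sessions-of-training protocol
#'
#' For each subject and repeat, samples `k` of the subject's sessions
#' without replacement, trains a subject-specific MLP on their windows,
#' and tests on all remaining sessions' windows. This is the protocol
#' that exposes electrode-shift generalization: train and test sessions
#' were recorded with different shifts.
#'
#' @param fm an `emg_features` table spanning at least `k + 1` sessions
#'   per subject.
#' @param k number of training sessions (1 to sessions - 1).
#' @param n_repeats resamplings of the k-session subset per subject.
#'   Distinct subsets are drawn whenever possible; if `n_repeats` reaches
#'   the number of available k-subsets, all of them are evaluated exactly
#'   once (e.g. exhaustive leave-one-session-out at `k = sessions - 1`).
#' @param seed integer seed driving subset sampling and network init.
#' @param n_hidden,maxit,decay passed to [train_mlp()].
#' @return a `session_eval`: `runs` (accuracy per subject x repeat, %),
#'   `mean_accuracy`, `sd_accuracy`, and the aggregate `confusion` matrix
#'   over all test windows.
#' @export
session_protocol_evaluate <- function(fm, k, n_repeats = 1L, seed = 1L,
                                      n_hidden = 17, maxit = 150,
                                      decay = 1e-3) {
  stopifnot(inherits(fm, "emg_features"))
  levels <- sort(unique(fm$posture_id))
  subjects <- sort(unique(fm$subject_id))
  runs <- list()
  cm <- matrix(0L, length(levels), length(levels),
               dimnames = list(levels, levels))
  ri <- 0L
  for (si in seq_along(subjects)) {
    fs <- feature_subset(fm, fm$subject_id == subjects[si])
    sessions <- sort(unique(fs$session_id))
    if (k < 1 || k >= length(sessions))
      stopf("k = %d must be in 1..%d (sessions - 1)", k,
            length(sessions) - 1)
    subsets <- draw_session_subsets(sessions, k, n_repeats,
                                    derive_seed(seed, si, 555L))
    for (rep_i in seq_along(subsets)) {
      rs <- derive_seed(seed, si, rep_i)
      train_sessions <- subsets[[rep_i]]
      tr <- feature_subset(fs, fs$session_id %in% train_sessions)
      te <- feature_subset(fs, !fs$session_id %in% train_sessions)
      dtr <- fm_xy(tr, levels)
      dte <- fm_xy(te, levels)
      model <- train_mlp(dtr$x, dtr$y, n_hidden = n_hidden,
                         seed = derive_seed(rs, 2L), maxit = maxit,
                         decay = decay)
      pred <- predict(model, dte$x)
      cmi <- confusion_matrix(dte$y, pred, levels)
      cm <- cm + cmi
      ri <- ri + 1L
      runs[[ri]] <- data.frame(
        subject_id = subjects[si], rep = rep_i, k = k,
        accuracy = confusion_accuracy(cmi),
        train_sessions = paste(sort(train_sessions), collapse = "+"))
    }
  }
  runs <- do.call(rbind, runs)
  structure(
    list(runs = runs, mean_accuracy = mean(runs$accuracy),
         sd_accuracy = sd(runs$accuracy), confusion = cm, k = k),
    class = "session_eval")
}

#' Stratified k-fold cross-validation of the MLP
#'
#' Windows are assigned to folds stratified by posture (seeded). This is
#' the auxiliary within-pool evaluation; it cannot expose electrode-shift
#' generalization because every fold mixes all sessions.
#'
#' @param fm an `emg_features` table.
#' @param n_folds folds (default 10).
#' @param seed,n_hidden,maxit,decay as in [session_protocol_evaluate()].
#' @return list with `per_fold` accuracies (%), `mean_accuracy`,
#'   `sd_accuracy`, aggregate `confusion`, and the `folds` assignment.
#' @export
kfold_cv <- function(fm, n_folds = 10L, seed = 1L, n_hidden = 17,
                     maxit = 150, decay = 1e-3) {
  stopifnot(inherits(fm, "emg_features"))
  if (nrow(fm) < n_folds) stopf("fewer rows (%d) than folds", nrow(fm))
  levels <- sort(unique(fm$posture_id))
  y <- factor(fm$posture_id, levels)
  fold <- integer(nrow(fm))
  small <- names(which(table(y) < n_folds))
  if (length(small))
    warnf("class(es) with fewer rows than folds (best-effort stratification): %s",
          paste(small, collapse = ", "))
  for (lv in levels) {
    idx <- which(y == lv)
    idx <- with_seed(derive_seed(seed, match(lv, levels)), sample(idx))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  acc <- numeric(n_folds)
  cm <- matrix(0L, length(levels), length(levels),
               dimnames = list(levels, levels))
  for (f in seq_len(n_folds)) {
    tr <- feature_subset(fm, fold != f)
    te <- feature_subset(fm, fold == f)
    dtr <- fm_xy(tr, levels)
    model <- train_mlp(dtr$x, dtr$y, n_hidden = n_hidden,
                       seed = derive_seed(seed, 99L, f), maxit = maxit,
                       decay = decay)
    pred <- predict(model, fm_xy(te, levels)$x)
    cmi <- confusion_matrix(factor(te$posture_id, levels), pred, levels)
    acc[f] <- confusion_accuracy(cmi)
    cm <- cm + cmi
  }
  list(per_fold = acc, mean_accuracy = mean(acc), sd_accuracy = sd(acc),
       confusion = cm, folds = fold)
}
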