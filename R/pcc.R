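# Pearson-correlation statistics for feature selection.
#
# The inter-session PCC measures how stable a feature's posture-by-channel
# signature is across wearing sessions (electrode shift); the inter-feature
# PCC measures information redundancy between features. Correlations are
# banded into weak/moderate/strong linear relationships.

# Session signature matrix for one subject: rows = sessions, columns =
# (posture x feature-dimension) mean values over that session's windows.
session_signatures <- function(fm_subject) {
  vcols <- attr(fm_subject, "value_cols")
  sessions <- sort(unique(fm_subject$session_id))
  postures <- sort(unique(fm_subject$posture_id))
  sig <- matrix(NA_real_, nrow = length(sessions),
                ncol = length(postures) * length(vcols),
                dimnames = list(sessions, NULL))
  for (si in seq_along(sessions)) {
    fs <- fm_subject[fm_subject$session_id == sessions[si], , drop = FALSE]
    have <- unique(fs$posture_id)
    gap <- setdiff(postures, have)
    if (length(gap))
      stopf("session %s of subject %s is missing posture(s): %s",
            sessions[si], fm_subject$subject_id[1],
            paste(gap, collapse = ", "))
    m <- vapply(postures, function(p)
      colMeans(as.matrix(fs[fs$posture_id == p, vcols, drop = FALSE])),
      numeric(length(vcols)))
    sig[si, ] <- as.vector(m)
  }
  sig
}

# Pearson r that treats zero-variance vectors as having no measurable
# linear association (r = 0) instead of NA, so sweep curves over degenerate
# thresholds stay defined.
safe_pearson <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(structure(0, zero_variance = TRUE))
  cor(a, b)
}

#' Inter-session PCC of a feature matrix
#'
#' For each subject and session, builds the session signature (mean
#' feature value per posture and channel dimension over that session's
#' windows, flattened to one vector), computes the Pearson correlation for
#' every unordered pair of sessions, and averages over pairs. With 10
#' sessions there are 45 pairs per subject.
#'
#' @param fm an `emg_features` table from [extract_features()], spanning
#'   at least 2 sessions per subject.
#' @return a `pcc_session` list: `per_pair` (subject, session pair, r),
#'   `per_subject` (subject, mean r over pairs), and `mean_r` (mean of the
#'   subject means).
#' @export
inter_session_pcc <- function(fm) {
  stopifnot(inherits(fm, "emg_features"))
  subjects <- sort(unique(fm$subject_id))
  pair_rows <- list()
  subj_means <- numeric(length(subjects))
  for (k in seq_along(subjects)) {
    fs <- feature_subset(fm, fm$subject_id == subjects[k])
    sig <- session_signatures(fs)
    if (nrow(sig) < 2L)
      stopf("subject %s has fewer than 2 sessions", subjects[k])
    pr <- combn(nrow(sig), 2)
    r <- vapply(seq_len(ncol(pr)), function(j)
      as.numeric(safe_pearson(sig[pr[1, j], ], sig[pr[2, j], ])), numeric(1))
    pair_rows[[k]] <- data.frame(
      subject_id = subjects[k],
      session_a = as.integer(rownames(sig))[pr[1, ]],
      session_b = as.integer(rownames(sig))[pr[2, ]], r = r)
    subj_means[k] <- mean(r)
  }
  structure(
    list(per_pair = do.call(rbind, pair_rows),
         per_subject = data.frame(subject_id = subjects, mean_r = subj_means),
         mean_r = mean(subj_means)),
    class = "pcc_session")
}

#' Inter-feature PCC matrix
#'
#' For each pair of features, the Pearson correlation between the two
#' features' values pooled over all (window, channel) observations, after
#' standardizing each feature per channel (so channel gain differences do
#' not dominate). Multi-dimensional features (AR/CC) contribute their
#' first dimension. Feature tables are aligned on common window
#' provenance (subject, session, posture, window start); tables whose
#' provenance differs beyond a common subset (e.g. MAVSLP, which drops
#' each trial's first window) are aligned on the intersection.
#'
#' @param fms named list of `emg_features` tables over the same dataset
#'   and windowing.
#' @return symmetric correlation matrix with unit diagonal, one row per
#'   feature.
#' @export
inter_feature_pcc <- function(fms) {
  stopifnot(is.list(fms), length(fms) >= 2L, !is.null(names(fms)))
  key_of <- function(fm) paste(fm$subject_id, fm$session_id, fm$posture_id,
                               fm$window_start, sep = "\r")
  keys <- lapply(fms, key_of)
  common <- Reduce(intersect, keys)
  if (!length(common))
    stopf("feature matrices share no common window provenance")
  pooled <- vapply(seq_along(fms), function(i) {
    fm <- fms[[i]]
    rows <- match(common, keys[[i]])
    vcols <- attr(fm, "value_cols")
    first_dim <- vcols[grep("^ch[0-9]+_[A-Za-z]+1?$", vcols)]
    if (length(first_dim) > 8L) first_dim <- vcols[seq_len(8)]
    if (!length(first_dim)) first_dim <- vcols[seq_len(min(8, length(vcols)))]
    m <- as.matrix(fm[rows, first_dim, drop = FALSE])
    as.vector(apply(m, 2, function(x)
      if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x)))
  }, numeric(length(common) * 8L))
  colnames(pooled) <- names(fms)
  r <- matrix(1, length(fms), length(fms),
              dimnames = list(names(fms), names(fms)))
  for (i in seq_along(fms)) for (j in seq_along(fms)) if (i < j) {
    rij <- as.numeric(safe_pearson(pooled[, i], pooled[, j]))
    r[i, j] <- rij
    r[j, i] <- rij
  }
  r
}

#' Band a correlation into weak/moderate/strong
#'
#' Linearity bands: weak `0 < r <= 0.3`, moderate `0.3 < r <= 0.7`,
#' strong `0.7 < r <= 1`. Non-positive correlations are banded as weak
#' and flagged in the `"negative"` attribute (the banding is defined on
#' positive association only).
#'
#' @param r numeric correlation(s) in `[-1, 1]`.
#' @return character vector of band labels with a logical `"negative"`
#'   attribute marking `r <= 0` entries.
#' @export
relationship_band <- function(r) {
  if (any(abs(r) > 1 + 1e-12))
    stopf("correlation outside [-1, 1]: %g", r[which.max(abs(r))])
  band <- ifelse(r > 0.7, "strong", ifelse(r > 0.3, "moderate", "weak"))
  structure(band, negative = r <= 0)
}
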