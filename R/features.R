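# Time-domain feature extraction.
#
# The 21 classic time-domain sEMG features, computed per channel on each
# analysis window, plus the Hudgins and Du feature combinations. The
# threshold-based counts (ZC, WAMP, MYOP, SSC) take their threshold from
# the R x resting-RMS rule. Formula conventions follow the printed
# time-domain definitions used throughout the myoelectric-control
# literature, with two long-standing repairs, both configurable in intent
# and documented in the methods vignette:
#   * ZC requires the sample product to be negative (a true sign change)
#     together with the amplitude condition |x_i - x_{i+1}| >= threshold;
#     thresholding the (negative) product itself could never fire.
#   * MYOP applies its indicator to |x_i|, since on a zero-mean signal a
#     one-sided indicator would only see positive excursions.
# VAR and SSI are uncentered second moments; AAC divides its N-1 absolute
# differences by N; MAV2's trailing taper 4(i - N)/N is signed; all exactly
# as conventionally printed.

.AMPLITUDE_FEATURES <- c("IEMG", "MAV", "MAV1", "MAV2", "SSI", "VAR",
                         "TM3", "TM4", "TM5", "RMS", "LOG", "WL", "AAC",
                         "DASDV")
.THRESHOLD_FEATURES <- c("ZC", "WAMP", "MYOP", "SSC")
.ORDER_FEATURES <- c("AR", "CC")
.COMBO_SETS <- list(HUDGINS = c("MAV", "WL", "ZC", "SSC"),
                    DU = c("IEMG", "VAR", "WL", "ZC", "SSC", "WAMP"))
# Default R factors outside threshold sweeps (best-performing values of the
# threshold optimization: 13.2, 9.9, 6.6, 13.2 mV at a 3.3 mV resting RMS).
.DEFAULT_R <- c(ZC = 4.0, WAMP = 3.0, MYOP = 2.0, SSC = 4.0)

#' Names of all time-domain feature extractors
#'
#' @param include_combos also append the combination sets `HUDGINS`
#'   (MAV, WL, ZC, SSC) and `DU` (IEMG, VAR, WL, ZC, SSC, WAMP).
#' @return character vector of the 21 extractor names (23 with combos).
#' @export
feature_names <- function(include_combos = FALSE) {
  nm <- c(.AMPLITUDE_FEATURES, "MAVSLP", .THRESHOLD_FEATURES, .ORDER_FEATURES)
  if (include_combos) nm <- c(nm, names(.COMBO_SETS))
  nm
}

#' The feature registry
#'
#' One row per extractor type: its kind, whether it needs a threshold
#' (ZC, WAMP, MYOP, SSC), a model order (AR, CC), and its output
#' dimensionality per channel (`NA` for order features, where it equals
#' the order).
#'
#' @return data.frame with columns `name`, `kind`, `needs_threshold`,
#'   `needs_order`, `dims_per_channel`.
#' @export
feature_registry <- function() {
  nm <- feature_names()
  data.frame(
    name = nm,
    kind = c(rep("amplitude", length(.AMPLITUDE_FEATURES)), "slope",
             rep("threshold", length(.THRESHOLD_FEATURES)),
             rep("order", length(.ORDER_FEATURES))),
    needs_threshold = nm %in% .THRESHOLD_FEATURES,
    needs_order = nm %in% .ORDER_FEATURES,
    dims_per_channel = ifelse(nm %in% .ORDER_FEATURES, NA_integer_, 1L),
    stringsAsFactors = FALSE
  )
}

#' Threshold grid from the R-factor rule
#'
#' Builds the threshold set `R * RMS_rest` for a grid of unitless factors
#' R. With the study values (resting RMS 3.3 mV, R from 0 to 10 in steps
#' of 0.5) the grid spans 0-33 mV in 21 steps of 1.65 mV.
#'
#' @param rest_rms resting-signal RMS in mV; must be positive.
#' @param R_min,R_max,R_step factor grid (default 0 to 10 by 0.5).
#' @return a `threshold_config`: list with `rest_rms`, `R_grid`,
#'   `thresholds` (mV).
#' @export
threshold_grid <- function(rest_rms, R_min = 0, R_max = 10, R_step = 0.5) {
  if (rest_rms <= 0) stopf("rest_rms must be positive, got %g", rest_rms)
  if (R_min > R_max) stopf("R_min must not exceed R_max")
  if (R_step <= 0) stopf("R_step must be positive")
  R <- seq(R_min, R_max, by = R_step)
  structure(list(rest_rms = rest_rms, R_grid = R, thresholds = R * rest_rms),
            class = "threshold_config")
}

# Piecewise MAV1/MAV2 weights for window length N (1-based sample index i;
# boundary samples at exactly 0.25N / 0.75N take weight 1, as printed).
mav_weights <- function(N, variant) {
  i <- seq_len(N)
  inner <- i >= 0.25 * N & i <= 0.75 * N
  if (variant == 1L) ifelse(inner, 1, 0.5)
  else ifelse(inner, 1, ifelse(i < 0.25 * N, 4 * i / N, 4 * (i - N) / N))
}

#' Amplitude-class features of one window
#'
#' Evaluates one of the 14 amplitude/shape formulas per channel.
#'
#' @param w an `emg_window` (from [segment_windows()]) or an 8 x N matrix.
#' @param name one of IEMG, MAV, MAV1, MAV2, SSI, VAR, TM3, TM4, TM5, RMS,
#'   LOG, WL, AAC, DASDV.
#' @param log_eps clamp for `log |x|` at exact zeros (LOG only).
#' @return numeric vector of 8 per-channel values.
#' @export
amplitude_features <- function(w, name, log_eps = 1e-12) {
  sig <- if (inherits(w, "emg_window")) w$samples else w
  name <- match.arg(name, .AMPLITUDE_FEATURES)
  vapply(seq_len(nrow(sig)), function(ch)
    window_feature_values(matrix(sig[ch, ], ncol = 1), name,
                          log_eps = log_eps)[1, 1],
    numeric(1))
}

#' Threshold-class features of one window
#'
#' ZC counts sign changes whose amplitude step reaches the threshold;
#' WAMP counts threshold-reaching amplitude steps; SSC counts slope-sign
#' products reaching the threshold; MYOP is the fraction of samples whose
#' magnitude reaches the threshold.
#'
#' @param w an `emg_window` or an 8 x N matrix.
#' @param name one of ZC, WAMP, MYOP, SSC.
#' @param threshold non-negative threshold in mV.
#' @return numeric vector of 8 per-channel values (integer counts; MYOP a
#'   fraction in `[0, 1]`).
#' @export
threshold_features <- function(w, name, threshold) {
  sig <- if (inherits(w, "emg_window")) w$samples else w
  name <- match.arg(name, .THRESHOLD_FEATURES)
  if (threshold < 0) stopf("threshold must be non-negative, got %g", threshold)
  vapply(seq_len(nrow(sig)), function(ch)
    window_feature_values(matrix(sig[ch, ], ncol = 1), name,
                          threshold = threshold)[1, 1],
    numeric(1))
}

# Column-wise feature evaluation on an N x K matrix of windowed samples
# (one channel, K windows). Returns a K x d matrix (d = 1, or `order`).
window_feature_values <- function(W, name, threshold = NULL, order = NULL,
                                  log_eps = 1e-12) {
  N <- nrow(W)
  as_col <- function(v) matrix(v, ncol = 1)
  switch(
    name,
    IEMG = as_col(colSums(abs(W))),
    MAV = as_col(colMeans(abs(W))),
    MAV1 = as_col(colMeans(mav_weights(N, 1L) * abs(W))),
    MAV2 = as_col(colMeans(mav_weights(N, 2L) * abs(W))),
    SSI = as_col(colSums(W^2)),
    VAR = as_col(colSums(W^2) / (N - 1)),
    TM3 = as_col(abs(colMeans(W^3))),
    TM4 = as_col(colMeans(W^4)),
    TM5 = as_col(abs(colMeans(W^5))),
    RMS = as_col(sqrt(colMeans(W^2))),
    LOG = as_col(exp(colMeans(log(pmax(abs(W), log_eps))))),
    WL = as_col(colSums(abs(diff(W)))),
    AAC = as_col(colSums(abs(diff(W))) / N),
    DASDV = as_col(sqrt(colSums(diff(W)^2) / (N - 1))),
    ZC = {
      D <- diff(W)
      P <- W[-N, , drop = FALSE] * W[-1, , drop = FALSE]
      as_col(colSums(P < 0 & abs(D) >= threshold))
    },
    WAMP = as_col(colSums(abs(diff(W)) >= threshold)),
    MYOP = as_col(colMeans(abs(W) >= threshold)),
    SSC = {
      A <- W[2:(N - 1), , drop = FALSE] - W[1:(N - 2), , drop = FALSE]
      B <- W[2:(N - 1), , drop = FALSE] - W[3:N, , drop = FALSE]
      as_col(colSums(A * B >= threshold))
    },
    AR = {
      v <- vapply(seq_len(ncol(W)), function(k)
        ar_model(W[, k], order)$coefficients, numeric(order))
      if (is.null(dim(v))) matrix(v, ncol = 1) else t(v)
    },
    CC = {
      v <- vapply(seq_len(ncol(W)), function(k)
        ar_model(W[, k], order)$cepstral, numeric(order))
      if (is.null(dim(v))) matrix(v, ncol = 1) else t(v)
    },
    stopf("unknown feature '%s'", name)
  )
}

#' Autoregressive model of a signal window
#'
#' Fits an AR(p) model `x_i = sum_{l=1..p} a_l x_{i-l} + w_i` by the
#' autocorrelation (Yule-Walker / Levinson-Durbin) method, without mean
#' removal, and attaches the cepstral coefficients derived from the AR
#' coefficients.
#'
#' @param x numeric signal vector (length > `order`).
#' @param order model order p, between 1 and 10.
#' @return an `ar_model`: list with `order`, `coefficients` (a_1..a_p) and
#'   `cepstral` (c_1..c_p). A degenerate all-zero window yields zero
#'   coefficients with a warning.
#' @export
ar_model <- function(x, order) {
  if (order < 1 || order > 10) stopf("AR order must be in 1..10, got %s", order)
  order <- as.integer(order)
  if (length(x) <= order)
    stopf("window length (%d) must exceed the AR order (%d)",
          length(x), order)
  if (all(x == 0) || stats::var(x) < .Machine$double.xmin) {
    warnf("degenerate (constant) window; returning zero AR coefficients")
    a <- numeric(order)
  } else {
    a <- as.numeric(ar.yw(x, aic = FALSE, order.max = order,
                          demean = FALSE)$ar)
  }
  structure(list(order = order, coefficients = a,
                 cepstral = cepstral_from_ar(a)),
            class = "ar_model")
}

#' Cepstral coefficients from AR coefficients
#'
#' Applies the recursion `c_1 = -a_1`,
#' `c_p = -a_p - sum_{l=1}^{p-1} (1 - l/p) a_l c_{p-l}`, i.e. the cepstrum
#' of the all-pole transfer function `1 / (1 + sum_l a_l z^-l)`.
#'
#' @param ar an `ar_model` or a numeric vector of AR coefficients.
#' @return numeric vector `c_1..c_p`.
#' @export
cepstral_from_ar <- function(ar) {
  a <- if (inherits(ar, "ar_model")) ar$coefficients else as.numeric(ar)
  p <- length(a)
  if (!p) return(numeric(0))
  cc <- numeric(p)
  cc[1] <- -a[1]
  if (p > 1) for (n in 2:p) {
    l <- 1:(n - 1)
    cc[n] <- -a[n] - sum((1 - l / n) * a[l] * cc[n - l])
  }
  cc
}

#' MAV slope across consecutive windows of a trial
#'
#' The difference of MAV between each analysis window and its predecessor
#' within one trial; the first window of each trial has no predecessor and
#' is dropped.
#'
#' @param mav_matrix K x C matrix of MAV values (windows in trial order).
#' @return (K-1) x C matrix of first differences; a single-window trial
#'   yields an empty matrix with a warning.
#' @export
mavslp <- function(mav_matrix) {
  mav_matrix <- as.matrix(mav_matrix)
  if (nrow(mav_matrix) < 2L) {
    warnf("MAVSLP needs at least 2 consecutive windows; trial dropped")
    return(mav_matrix[0, , drop = FALSE])
  }
  diff(mav_matrix)
}

# Resolve the threshold (mV) for a threshold feature.
resolve_threshold <- function(name, threshold, threshold_R, rest_rms,
                              dataset) {
  if (!is.null(threshold)) {
    if (threshold < 0) stopf("threshold must be non-negative")
    return(threshold)
  }
  R <- threshold_R %||% .DEFAULT_R[[name]]
  rr <- rest_rms %||%
    tryCatch(measure_rest_rms(dataset, by_subject = FALSE),
             error = function(e) dataset$config$rest_rms)
  R * rr
}

#' Extract a labeled feature matrix from a dataset
#'
#' Runs the full per-trial pipeline: band-pass filtering (skipped when the
#' dataset has already been through [preprocess_dataset()]), sliding-window
#' segmentation, and per-channel feature evaluation. One row per window;
#' `8 x dims_per_channel` feature columns named `ch<c>_<feature>` (with a
#' dimension suffix for AR/CC); label columns `subject_id`, `session_id`,
#' `posture_id`, `window_start` carry provenance.
#'
#' @param dataset an `emg_dataset`.
#' @param feature one of [feature_names()] or a combination (`"HUDGINS"`,
#'   `"DU"`).
#' @param threshold threshold in mV for ZC/WAMP/MYOP/SSC; when `NULL` it is
#'   derived as `threshold_R * rest_rms`, measuring the resting RMS from
#'   the dataset's rest trials if `rest_rms` is not given.
#' @param threshold_R unitless R factor (defaults per feature: ZC 4.0,
#'   WAMP 3.0, MYOP 2.0, SSC 4.0).
#' @param rest_rms resting RMS in mV used by the threshold rule.
#' @param order AR/CC model order (default 2, the best-performing order).
#' @param window_ms,shift_ms analysis window size and shift.
#' @param filter apply the band-pass filter to unfiltered datasets.
#' @param log_eps zero clamp for the LOG detector.
#' @return an `emg_features` data.frame; attributes `feature`,
#'   `value_cols`, `threshold`, `order`, `window_ms`, `shift_ms`.
#' @export
extract_features <- function(dataset, feature, threshold = NULL,
                             threshold_R = NULL, rest_rms = NULL,
                             order = 2L, window_ms = 250, shift_ms = 10,
                             filter = TRUE, log_eps = 1e-12) {
  stopifnot(inherits(dataset, "emg_dataset"))
  feature <- match.arg(feature, feature_names(include_combos = TRUE))
  rates <- unique(vapply(dataset$recordings, `[[`, numeric(1),
                         "sampling_rate"))
  if (length(rates) != 1L)
    stopf("mixed sampling rates in dataset: %s", paste(rates, collapse = ", "))

  if (feature %in% names(.COMBO_SETS)) {
    parts <- lapply(.COMBO_SETS[[feature]], function(f)
      extract_features(dataset, f, threshold = threshold,
                       threshold_R = threshold_R, rest_rms = rest_rms,
                       order = order, window_ms = window_ms,
                       shift_ms = shift_ms, filter = filter,
                       log_eps = log_eps))
    label_cols <- c("subject_id", "session_id", "posture_id", "window_start")
    out <- parts[[1]][label_cols]
    vcols <- character(0)
    for (p in parts) {
      out <- cbind(out, p[attr(p, "value_cols")])
      vcols <- c(vcols, attr(p, "value_cols"))
    }
    return(structure(out, feature = feature, value_cols = vcols,
                     window_ms = window_ms, shift_ms = shift_ms,
                     class = c("emg_features", "data.frame")))
  }

  if (feature %in% .THRESHOLD_FEATURES)
    threshold <- resolve_threshold(feature, threshold, threshold_R,
                                   rest_rms, dataset)

  do_filter <- filter && !isTRUE(dataset$filtered)
  base <- if (feature == "MAVSLP") "MAV" else feature
  dims <- if (feature %in% .ORDER_FEATURES) as.integer(order) else 1L
  vcols <- if (dims == 1L) sprintf("ch%d_%s", 1:8, feature)
           else as.vector(t(outer(1:8, seq_len(dims),
                                  function(c, d) sprintf("ch%d_%s%d", c, feature, d))))

  blocks <- vector("list", length(dataset$recordings))
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    if (do_filter) rec <- bandpass_filter(rec)
    wm <- window_matrices(rec, window_ms, shift_ms)
    if (!length(wm$starts)) next
    vals <- do.call(cbind, lapply(wm$W, window_feature_values, name = base,
                                  threshold = threshold, order = order,
                                  log_eps = log_eps))
    starts <- wm$starts
    if (feature == "MAVSLP") {
      vals <- mavslp(vals)
      starts <- starts[-1]
      if (!nrow(vals)) next
    }
    colnames(vals) <- vcols
    blocks[[i]] <- data.frame(
      subject_id = rec$subject_id, session_id = rec$session_id,
      posture_id = rec$posture_id, window_start = starts, vals,
      check.names = FALSE)
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  rownames(out) <- NULL
  if (anyNA(out[vcols]) || any(!is.finite(as.matrix(out[vcols]))))
    stopf("non-finite feature values produced for %s", feature)
  structure(out, feature = feature, value_cols = vcols,
            threshold = threshold, order = if (dims > 1L) dims,
            window_ms = window_ms, shift_ms = shift_ms,
            class = c("emg_features", "data.frame"))
}

# Keep attributes when subsetting rows of an emg_features table.
feature_subset <- function(fm, keep) {
  out <- fm[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("feature", "value_cols", "threshold", "order",
              "window_ms", "shift_ms"))
    attr(out, a) <- attr(fm, a)
  class(out) <- class(fm)
  out
}
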