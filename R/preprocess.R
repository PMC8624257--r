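# Band-pass filtering and sliding-window segmentation.

#' Zero-phase band-pass filter a recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass per
#' channel. With the 500 Hz armband sampling rate the physiological
#' 15-250 Hz band has its upper edge exactly at Nyquist, which is invalid
#' for IIR design; the default upper edge is therefore 249 Hz.
#' Forward-backward filtering doubles the effective order.
#'
#' @param rec an [emg_recording].
#' @param low,high band edges in Hz; must satisfy `0 < low < high <
#'   sampling_rate / 2`.
#' @param order Butterworth design order (default 4).
#' @return the recording with filtered signal (same shape and metadata).
#' @export
bandpass_filter <- function(rec, low = 15, high = 249, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high))
    stopf("band edges must satisfy 0 < low < high (got %g, %g)", low, high)
  if (high >= nyq)
    stopf("upper band edge %g Hz is at or above Nyquist (%g Hz); use e.g. %g Hz",
          high, nyq, nyq - 1)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  n <- ncol(rec$signal)
  pad <- min(n - 1L, 300L)
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(x) {
    # odd-symmetric reflection padding suppresses filtfilt edge transients
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }))
  out
}

#' Band-pass filter every recording of a dataset
#'
#' @param dataset an `emg_dataset`.
#' @inheritParams bandpass_filter
#' @return the dataset with all recordings filtered and its `filtered`
#'   flag set (downstream extraction then skips re-filtering).
#' @export
preprocess_dataset <- function(dataset, low = 15, high = 249, order = 4) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dataset$recordings <- lapply(dataset$recordings, bandpass_filter,
                               low = low, high = high, order = order)
  dataset$filtered <- TRUE
  dataset
}

# Window start offsets (0-based samples) and length for a trial.
window_plan <- function(n_samples, sampling_rate, window_ms, shift_ms) {
  N <- as.integer(round(window_ms * sampling_rate / 1000))
  step <- as.integer(round(shift_ms * sampling_rate / 1000))
  if (step < 1L) stopf("window shift must be at least one sample")
  if (n_samples < N) return(list(N = N, step = step, starts = integer(0)))
  list(N = N, step = step, starts = seq.int(0L, n_samples - N, by = step))
}

#' Segment a recording into overlapping analysis windows
#'
#' Windows are closed-open sample intervals `[start, start + N)` at starts
#' `0, shift, 2 shift, ...` while fully inside the trial. At the defaults
#' (250 ms window, 10 ms shift, 500 Hz) a 5-s trial yields 476 windows of
#' 125 samples.
#'
#' @param rec an [emg_recording].
#' @param window_ms window size in milliseconds.
#' @param shift_ms window shift in milliseconds.
#' @return list of `emg_window` objects, each with `samples` (8 x N),
#'   `start_index` (0-based), and the parent recording's labels. A trial
#'   shorter than one window yields an empty list with a warning.
#' @export
segment_windows <- function(rec, window_ms = 250, shift_ms = 10) {
  stopifnot(inherits(rec, "emg_recording"))
  wp <- window_plan(ncol(rec$signal), rec$sampling_rate, window_ms, shift_ms)
  if (!length(wp$starts)) {
    warnf("trial (%d samples) shorter than one window (%d samples); no windows emitted",
          ncol(rec$signal), wp$N)
    return(list())
  }
  lapply(wp$starts, function(s0) {
    structure(
      list(samples = rec$signal[, (s0 + 1):(s0 + wp$N), drop = FALSE],
           start_index = s0,
           subject_id = rec$subject_id, session_id = rec$session_id,
           posture_id = rec$posture_id),
      class = "emg_window")
  })
}

# Fast path: per-channel N x K windowed matrices for one recording.
window_matrices <- function(rec, window_ms, shift_ms) {
  wp <- window_plan(ncol(rec$signal), rec$sampling_rate, window_ms, shift_ms)
  if (!length(wp$starts)) return(list(starts = integer(0), N = wp$N, W = NULL))
  idx <- outer(seq_len(wp$N), wp$starts, `+`)
  W <- lapply(seq_len(8), function(ch)
    matrix(rec$signal[ch, idx], nrow = wp$N))
  list(starts = wp$starts, N = wp$N, W = W)
}
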