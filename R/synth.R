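# Synthetic armband sEMG generation.
#
# Signal model: each channel of a trial is zero-mean band-limited Gaussian
# noise whose RMS amplitude is set by the posture's activation profile,
# sampled at the channel's *shifted* angular position on the 8-electrode
# ring. Electrode shift between wearing sessions is a fractional circular
# rotation of the ring plus small multiplicative per-channel gain jitter
# (electrode-skin impedance changes). No motor-unit-level structure is
# simulated: the time-domain features under study depend only on the
# envelope and the spectral band.

#' Synthetic dataset configuration
#'
#' Defaults emulate the study conditions of the armband protocol:
#' 500 Hz sampling, 5-s static trials at 20% maximum voluntary contraction
#' (MVC), 10 wearing sessions per subject with electrode shift, and a
#' 3.3 mV resting RMS.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions wearing sessions per subject (don/doff between them).
#' @param trial_duration trial length in seconds.
#' @param sampling_rate sampling frequency in Hz.
#' @param rest_rms resting-channel RMS amplitude in mV.
#' @param mvc_fraction contraction level as a fraction of MVC; the envelope
#'   gain is calibrated so that 20% MVC gives a fully activated channel an
#'   RMS of `5 * rest_rms`, linearly in `mvc_fraction`.
#' @param shift_sd SD of the per-session circular rotation offset, in
#'   channel widths (1 channel = 45 degrees of the ring).
#' @param gain_jitter_sd SD of log per-channel multiplicative gain jitter.
#' @param noise_band two-sided spectral support of the signal in Hz.
#' @param master_seed integer master seed for the whole dataset.
#' @return a `synth_config` object (named list).
#' @export
synth_config <- function(n_subjects = 3, n_sessions = 10, trial_duration = 5,
                         sampling_rate = 500, rest_rms = 3.3,
                         mvc_fraction = 0.20, shift_sd = 0.5,
                         gain_jitter_sd = 0.015, noise_band = c(15, 249),
                         master_seed = 1L) {
  if (sampling_rate <= 2 * noise_band[2])
    stopf("sampling_rate (%g Hz) must exceed twice the upper noise band edge (%g Hz)",
          sampling_rate, noise_band[2])
  if (noise_band[1] <= 0 || noise_band[1] >= noise_band[2])
    stopf("noise_band must satisfy 0 < low < high")
  n <- trial_duration * sampling_rate
  if (abs(n - round(n)) > 1e-9)
    stopf("trial_duration x sampling_rate must be an integer sample count")
  if (rest_rms <= 0) stopf("rest_rms must be positive")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         trial_duration = trial_duration, sampling_rate = sampling_rate,
         rest_rms = rest_rms, mvc_fraction = mvc_fraction,
         shift_sd = shift_sd, gain_jitter_sd = gain_jitter_sd,
         noise_band = as.numeric(noise_band),
         master_seed = as.integer(master_seed)),
    class = "synth_config"
  )
}

#' Per-session electrode-shift model
#'
#' @param rotation_offset fractional circular channel offset; any real
#'   value, taken modulo 8 (offset 8 is identical to 0).
#' @param gain_jitter_sd SD of log multiplicative per-channel gain.
#' @param session_seed integer seed from which the 8 gain multipliers are
#'   drawn (log-normal, hence strictly positive).
#' @return a `shift_model` object with fields `rotation_offset`, `gains`.
#' @export
shift_model <- function(rotation_offset = 0, gain_jitter_sd = 0,
                        session_seed = 1L) {
  if (gain_jitter_sd < 0) stopf("gain_jitter_sd must be non-negative")
  gains <- if (gain_jitter_sd == 0) rep(1, 8)
           else with_seed(session_seed, exp(rnorm(8, 0, gain_jitter_sd)))
  structure(
    list(rotation_offset = rotation_offset %% 8,
         gain_jitter_sd = gain_jitter_sd,
         session_seed = as.integer(session_seed),
         gains = gains),
    class = "shift_model"
  )
}

# Circular linear interpolation of an 8-point ring profile at the shifted
# channel positions (0-based positions channel-1 + offset, modulo 8).
shifted_activation <- function(profile, rotation_offset) {
  pos <- ((0:7) + rotation_offset) %% 8
  i0 <- floor(pos)
  frac <- pos - i0
  (1 - frac) * profile[i0 + 1] + frac * profile[(i0 + 1) %% 8 + 1]
}

# Band-limited unit-variance Gaussian noise via FFT-domain masking of white
# noise. Exact spectral support, zero mean (DC bin removed).
band_limited_noise <- function(n, sampling_rate, band) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) * sampling_rate / n
  keep <- (freqs >= band[1] & freqs <= band[2]) |
          (freqs >= sampling_rate - band[2] & freqs <= sampling_rate - band[1])
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

#' Construct an EMG recording object
#'
#' @param signal 8 x N numeric matrix, mV.
#' @param sampling_rate Hz.
#' @param subject_id,session_id,posture_id annotations.
#' @return an `emg_recording`.
#' @export
emg_recording <- function(signal, sampling_rate, subject_id, session_id,
                          posture_id) {
  if (!is.matrix(signal) || nrow(signal) != 8L)
    stopf("signal must be an 8 x N matrix")
  if (anyNA(signal)) stopf("signal contains missing samples")
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         subject_id = subject_id, session_id = session_id,
         posture_id = posture_id),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, session %s, posture %s: 8 x %d @ %g Hz\n",
              x$subject_id, x$session_id, x$posture_id, ncol(x$signal),
              x$sampling_rate))
  invisible(x)
}

#' Synthesize one trial
#'
#' Generates an 8-channel recording of one static posture held for the
#' configured trial duration. Each channel is band-limited Gaussian noise
#' calibrated so its RMS equals
#' `rest_rms * (1 + (active_gain - 1) * a_c) * gain_c`, where `a_c` is the
#' archetype's activation interpolated at the channel's shifted ring
#' position and `active_gain = 1 + 4 * mvc_fraction / 0.2`.
#'
#' @param archetype a [posture_archetype].
#' @param shift a [shift_model] for the session.
#' @param config a [synth_config].
#' @param seed integer trial seed; identical seeds give identical signals.
#' @return an [emg_recording].
#' @export
synthesize_trial <- function(archetype, shift, config, seed = 1L) {
  stopifnot(inherits(archetype, "posture_archetype"),
            inherits(shift, "shift_model"),
            inherits(config, "synth_config"))
  n <- as.integer(round(config$trial_duration * config$sampling_rate))
  act <- shifted_activation(archetype$activation_profile,
                            shift$rotation_offset)
  active_gain <- 1 + 4 * config$mvc_fraction / 0.2
  target_rms <- config$rest_rms * (1 + (active_gain - 1) * act) * shift$gains
  sig <- with_seed(seed, {
    t(vapply(seq_len(8), function(ch) {
      x <- band_limited_noise(n, config$sampling_rate, config$noise_band)
      x / sqrt(mean(x^2)) * target_rms[ch]
    }, numeric(n)))
  })
  emg_recording(sig, config$sampling_rate, subject_id = NA_integer_,
                session_id = NA_integer_, posture_id = archetype$posture_id)
}

#' Generate a multi-subject, multi-session dataset
#'
#' Every subject wears the armband at the marked reference position; each
#' of `n_sessions` sessions draws a fresh [shift_model] whose rotation
#' offset is Normal(0, `shift_sd`) around that reference (the don/doff
#' placement error), plus per-channel gain jitter. Each session contains
#' one trial per requested posture in a session-specific random order.
#' Fully reproducible from `config$master_seed`.
#'
#' @param config a [synth_config].
#' @param postures posture ids to include, or a group label for
#'   [group_postures()]; default all 12.
#' @return an `emg_dataset`: list with `recordings` (list of
#'   [emg_recording]), `manifest` (data.frame with subject, session,
#'   posture, trial order, seed and rotation offset) and `config`.
#' @export
generate_dataset <- function(config, postures = posture_ids()) {
  stopifnot(inherits(config, "synth_config"))
  postures <- group_postures(postures)
  if (!length(postures)) stopf("postures must be non-empty")
  catalog <- default_archetype_catalog()
  recs <- list()
  rows <- list()
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (sess in seq_len(config$n_sessions)) {
      sess_seed <- derive_seed(config$master_seed, s, sess)
      rot <- if (config$shift_sd == 0) 0 else
        with_seed(derive_seed(sess_seed, 1L),
                  rnorm(1, 0, config$shift_sd))
      shift <- shift_model(rot, config$gain_jitter_sd,
                           session_seed = derive_seed(sess_seed, 2L))
      order_idx <- with_seed(derive_seed(sess_seed, 3L),
                             sample(seq_along(postures)))
      for (j in seq_along(order_idx)) {
        pid <- postures[order_idx[j]]
        trial_seed <- derive_seed(sess_seed, 4L, order_idx[j])
        rec <- synthesize_trial(catalog[[pid]], shift, config, trial_seed)
        rec$subject_id <- s
        rec$session_id <- sess
        idx <- idx + 1L
        recs[[idx]] <- rec
        rows[[idx]] <- data.frame(
          subject_id = s, session_id = sess, posture_id = pid,
          trial_order = j, seed = trial_seed,
          rotation_offset = shift$rotation_offset)
      }
    }
  }
  structure(
    list(recordings = recs, manifest = do.call(rbind, rows),
         config = config, filtered = FALSE),
    class = "emg_dataset"
  )
}

#' @export
print.emg_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<emg_dataset> %d trials: %d subject(s) x %d session(s) x %d posture(s)%s\n",
              nrow(m), length(unique(m$subject_id)),
              length(unique(m$session_id)),
              length(unique(m$posture_id)),
              if (isTRUE(x$filtered)) " [band-pass filtered]" else ""))
  invisible(x)
}

#' Measure the resting-channel RMS of a dataset
#'
#' Pools all samples of all rest-posture recordings and returns their RMS
#' in mV, either per subject or pooled across subjects. This is the
#' quantity the R-factor threshold rule scales.
#'
#' @param dataset an `emg_dataset`.
#' @param by_subject if `TRUE` (default) return a named vector, one RMS per
#'   subject; otherwise a single pooled value.
#' @return numeric RMS value(s) in mV.
#' @export
measure_rest_rms <- function(dataset, by_subject = TRUE) {
  is_rest <- dataset$manifest$posture_id == "rest"
  if (!any(is_rest))
    stopf("dataset contains no rest trials; cannot measure resting RMS")
  rest <- dataset$recordings[is_rest]
  subj <- dataset$manifest$subject_id[is_rest]
  rms_of <- function(rl) sqrt(mean(unlist(lapply(rl, function(r) r$signal^2))))
  if (by_subject)
    vapply(split(rest, subj), rms_of, numeric(1))
  else rms_of(rest)
}

# Subset a dataset to given postures (error on unknown) or subjects.
subset_dataset <- function(dataset, postures = NULL, subjects = NULL) {
  keep <- rep(TRUE, nrow(dataset$manifest))
  if (!is.null(postures)) {
    postures <- group_postures(postures)
    missing <- setdiff(postures, unique(dataset$manifest$posture_id))
    if (length(missing))
      stopf("dataset is missing posture(s): %s", paste(missing, collapse = ", "))
    keep <- keep & dataset$manifest$posture_id %in% postures
  }
  if (!is.null(subjects))
    keep <- keep & dataset$manifest$subject_id %in% subjects
  out <- dataset
  out$recordings <- dataset$recordings[keep]
  out$manifest <- dataset$manifest[keep, , drop = FALSE]
  rownames(out$manifest) <- NULL
  out
}
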