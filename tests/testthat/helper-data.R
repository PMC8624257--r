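# Small fixtures built in code, and memoized desk-scale study runs shared
# between the experiment tests and the acceptance suite.

# A recording with known content.
make_recording <- function(signal, fs = 500, subject = 1, session = 1,
                           posture = "rest") {
  emg_recording(signal, fs, subject, session, posture)
}

# A minimal emg_features table built by hand (for PCC unit tests).
make_fm <- function(df, value_cols, feature = "MAV") {
  structure(df, feature = feature, value_cols = value_cols,
            window_ms = 250, shift_ms = 10,
            class = c("emg_features", "data.frame"))
}

# Tiny but classifier-viable dataset: short trials, coarse windows.
tiny_dataset <- function(postures = c("rest", "cylindrical_grasp"),
                         n_subjects = 1, n_sessions = 3, seed = 42,
                         trial_duration = 2, shift_sd = 0.5) {
  cfg <- synth_config(n_subjects = n_subjects, n_sessions = n_sessions,
                      trial_duration = trial_duration, shift_sd = shift_sd,
                      master_seed = seed)
  generate_dataset(cfg, postures = postures)
}

.study_cache <- new.env(parent = emptyenv())

# Shift-vs-training study: 5 synthetic datasets at the study conditions
# (3 subjects, 10 sessions, shift_sd 0.5), MAV evaluated at k = 1, 4, 9
# and RMS / MAVSLP at k = 4, with inter-session PCC per feature.
shift_training_run <- function() {
  if (!is.null(.study_cache$shift)) return(.study_cache$shift)
  runs <- list()
  pccs <- list()
  for (seed in 1:5) {
    cfg <- synth_config(n_subjects = 3, n_sessions = 10, shift_sd = 0.5,
                        master_seed = 1000 + seed)
    ds <- preprocess_dataset(generate_dataset(cfg, postures = "G1"))
    fms <- list(
      MAV = extract_features(ds, "MAV", shift_ms = 100, filter = FALSE),
      RMS = extract_features(ds, "RMS", shift_ms = 100, filter = FALSE),
      MAVSLP = extract_features(ds, "MAVSLP", shift_ms = 100,
                                filter = FALSE))
    for (f in names(fms))
      pccs[[paste(seed, f)]] <- data.frame(
        seed = seed, feature = f, mean_r = inter_session_pcc(fms[[f]])$mean_r)
    plan <- rbind(
      data.frame(feature = "MAV", k = c(1, 4, 9), n_repeats = c(6, 6, 10)),
      data.frame(feature = c("RMS", "MAVSLP"), k = 4, n_repeats = 3))
    for (i in seq_len(nrow(plan))) {
      ev <- session_protocol_evaluate(
        fms[[plan$feature[i]]], plan$k[i], n_repeats = plan$n_repeats[i],
        seed = derive_seed(seed, i))
      runs[[paste(seed, i)]] <- cbind(seed = seed,
                                      feature = plan$feature[i], ev$runs)
    }
  }
  .study_cache$shift <- list(runs = do.call(rbind, runs),
                             pcc = do.call(rbind, pccs))
  .study_cache$shift
}

# Posture-group study: 5 datasets with all 12 postures; MAV at k = 4 for
# groups G1, G2, G3, G7.
group_comparison_run <- function() {
  if (!is.null(.study_cache$group)) return(.study_cache$group)
  tables <- list()
  runs <- list()
  cms <- NULL
  for (seed in 1:5) {
    cfg <- synth_config(n_subjects = 3, n_sessions = 10, shift_sd = 0.5,
                        master_seed = 2000 + seed)
    ds <- generate_dataset(cfg)
    rep <- run_group_comparison(ds, "MAV", groups = c("G1", "G2", "G3", "G7"),
                                k = 4, seed = seed)
    tables[[seed]] <- cbind(seed = seed, rep$table)
    runs[[seed]] <- cbind(seed = seed, rep$runs)
    cms <- if (is.null(cms)) rep$confusions
           else Map(`+`, cms, rep$confusions)
  }
  .study_cache$group <- list(table = do.call(rbind, tables),
                             runs = do.call(rbind, runs), confusions = cms)
  .study_cache$group
}

# WAMP threshold sweep over the full 21-point R grid, 3 datasets of 2
# subjects each, averaged per grid point.
threshold_sweep_run <- function() {
  if (!is.null(.study_cache$threshold)) return(.study_cache$threshold)
  tabs <- list()
  for (seed in 1:3) {
    cfg <- synth_config(n_subjects = 2, n_sessions = 10, shift_sd = 0.5,
                        master_seed = 3000 + seed)
    ds <- generate_dataset(cfg, postures = "G1")
    rep <- run_threshold_sweep(ds, "WAMP", group = "G1", k = 4, seed = seed)
    tabs[[seed]] <- cbind(seed = seed, rep$table)
  }
  all <- do.call(rbind, tabs)
  avg <- aggregate(cbind(mean_accuracy, mean_pcc, mean_threshold_mV) ~ R,
                   all, mean)
  .study_cache$threshold <- list(all = all, avg = avg[order(avg$R), ])
  .study_cache$threshold
}
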