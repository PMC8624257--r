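# Plain-text dataset and feature-table I/O.
#
# A dataset on disk is a directory: config.yaml (generator settings),
# manifest.csv (one row per trial: identifiers, seed, rotation offset,
# trial file), and trials/trial_NNNN.csv (samples x 8 channel columns).

#' Write a dataset to a directory
#'
#' @param dataset an `emg_dataset`.
#' @param dir output directory (created if needed).
#' @param digits significant digits for signal values.
#' @return `dir`, invisibly.
#' @export
write_emg_dataset <- function(dataset, dir, digits = 8) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dir.create(file.path(dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- dataset$manifest
  manifest$trial_file <- sprintf("trials/trial_%04d.csv",
                                 seq_len(nrow(manifest)))
  for (i in seq_along(dataset$recordings)) {
    sig <- t(dataset$recordings[[i]]$signal)
    colnames(sig) <- sprintf("ch%d", 1:8)
    write.csv(signif(sig, digits), file.path(dir, manifest$trial_file[i]),
              row.names = FALSE)
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(dataset$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_emg_dataset()]
#'
#' @param dir dataset directory.
#' @return an `emg_dataset`.
#' @export
read_emg_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(synth_config, cfg[setdiff(names(cfg), character(0))])
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    sig <- t(as.matrix(read.csv(file.path(dir, manifest$trial_file[i]))))
    dimnames(sig) <- NULL
    emg_recording(sig, config$sampling_rate,
                  subject_id = manifest$subject_id[i],
                  session_id = manifest$session_id[i],
                  posture_id = manifest$posture_id[i])
  })
  structure(list(recordings = recs,
                 manifest = manifest[setdiff(names(manifest), "trial_file")],
                 config = config, filtered = FALSE),
            class = "emg_dataset")
}

#' Write a feature matrix as CSV
#'
#' Labels and provenance first, then the named channel/feature columns.
#'
#' @param fm an `emg_features` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "emg_features"))
  write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}
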