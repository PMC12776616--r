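#' Write per-trial stimulus features to TSV
#'
#' One file per trial with columns `time_s`, `pitch_z`, `envelope`.
#'
#' @param sf a [stimulus_features()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(sf, path) {
  stopifnot(inherits(sf, "stimulus_features"))
  df <- data.frame(time_s = (seq_along(sf$pitch) - 1L) / sf$fs,
                   pitch_z = sf$pitch, envelope = sf$envelope)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-trial stimulus features from TSV
#'
#' @param path TSV file with columns `time_s`, `pitch_z`, `envelope`.
#' @param trial_id identifier to attach (defaults to the file name).
#' @return A [stimulus_features()]; `fs` is inferred from the time column.
#' @export
read_features_tsv <- function(path, trial_id = basename(path)) {
  df <- utils::read.delim(path)
  need <- c("time_s", "pitch_z", "envelope")
  if (!all(need %in% names(df))) {
    stop("feature file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fs <- 1 / stats::median(diff(df$time_s))
  stimulus_features(df$pitch_z, df$envelope, fs = round(fs, 6),
                    trial_id = trial_id)
}

#' Write an epoch set to a self-describing directory container
#'
#' Plain-text layout mirroring grouped array storage: `eeg/trial_NN.tsv`
#' (samples x channels, labeled header), `features/trial_NN.tsv`, and a
#' `meta.json` carrying `fs`, `channel_labels` and `onset_trim_s`.
#'
#' @param es an `epoch_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_dir <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "features"), showWarnings = FALSE)
  for (i in seq_along(es$epochs)) {
    ep <- es$epochs[[i]]
    tag <- sprintf("trial_%02d.tsv", i)
    eeg <- as.data.frame(t(ep$eeg))
    names(eeg) <- es$channel_labels
    utils::write.table(eeg, file.path(dir, "eeg", tag), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    feat <- data.frame(time_s = (seq_along(ep$pitch) - 1L) / es$fs,
                       pitch_z = ep$pitch, envelope = ep$envelope)
    utils::write.table(feat, file.path(dir, "features", tag), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  meta <- list(fs = es$fs, channel_labels = es$channel_labels,
               onset_trim_s = es$onset_trim, n_epochs = length(es$epochs))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read an epoch set written by [write_epoch_dir()]
#'
#' @param dir directory containing `meta.json`, `eeg/` and `features/`.
#' @return An `epoch_set`.
#' @export
read_epoch_dir <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  files <- sort(list.files(file.path(dir, "eeg"), pattern = "^trial_.*\\.tsv$"))
  epochs <- lapply(files, function(f) {
    eeg <- t(as.matrix(utils::read.delim(file.path(dir, "eeg", f),
                                         check.names = FALSE)))
    feat <- utils::read.delim(file.path(dir, "features", f))
    list(eeg = eeg, pitch = feat$pitch_z, envelope = feat$envelope,
         trial_id = sub("\\.tsv$", "", f))
  })
  structure(list(epochs = epochs, fs = meta$fs,
                 channel_labels = meta$channel_labels,
                 onset_trim = meta$onset_trim_s),
            class = "epoch_set")
}

#' Write categorization trial tables to TSV
#'
#' @param trials data frame with columns `participant`, `task`,
#'   `pitch_level`, `duration_level`, `response` (and optionally `block`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read categorization trial tables from TSV
#'
#' @param path TSV produced by [write_trials_tsv()] or equivalent.
#' @return A data frame of trials.
#' @export
read_trials_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("participant", "task", "pitch_level", "duration_level", "response")
  if (!all(need %in% names(df))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
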