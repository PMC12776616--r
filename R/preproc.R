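#' Multi-channel EEG recording
#'
#' Container for a continuous (or epoched) multi-channel EEG segment.  Data
#' are stored channels x samples, with ordered 10-20 channel labels and a
#' record of the current reference.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per data row.
#' @param reference_labels character vector naming the reference channels
#'   (e.g. the earlobe electrodes), or a descriptive tag such as
#'   `"average-ears"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          reference_labels = character(0)) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per data row", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("`channel_labels` must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs,
         channel_labels = as.character(channel_labels),
         reference_labels = as.character(reference_labels)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (length(x$reference_labels)) {
                paste(x$reference_labels, collapse = ",")
              } else "none"))
  invisible(x)
}

#' Per-trial stimulus features (pitch contour and amplitude envelope)
#'
#' @param pitch numeric vector; pitch contour, conventionally z-scored over
#'   the trial before modeling.
#' @param envelope numeric vector of the same length; amplitude envelope,
#'   nonnegative before any z-scoring.
#' @param fs sampling rate in Hz (128 Hz throughout the analysis).
#' @param trial_id identifier for the trial.
#' @return An object of class `stimulus_features`.
#' @export
stimulus_features <- function(pitch, envelope, fs, trial_id = NA_character_) {
  if (length(pitch) != length(envelope)) {
    stop("`pitch` and `envelope` must have the same length", call. = FALSE)
  }
  if (any(envelope < 0)) {
    stop("`envelope` must be nonnegative", call. = FALSE)
  }
  structure(list(pitch = as.numeric(pitch), envelope = as.numeric(envelope),
                 fs = fs, trial_id = trial_id),
            class = "stimulus_features")
}

#' Re-reference an EEG recording
#'
#' Subtracts, at every sample, the mean of the named reference channels from
#' every channel (offline re-referencing, e.g. to the average of the earlobe
#' electrodes).
#'
#' @param rec an [eeg_recording()].
#' @param ref_labels labels of the channels to average as the new reference;
#'   must all be present in `rec$channel_labels`.
#' @return A re-referenced `eeg_recording` with `reference_labels` updated.
#' @export
rereference <- function(rec, ref_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ref <- setdiff(ref_labels, rec$channel_labels)
  if (length(missing_ref)) {
    stop("unknown reference channel(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  idx <- match(ref_labels, rec$channel_labels)
  ref <- if (length(idx) == 1L) rec$data[idx, ] else colMeans(rec$data[idx, , drop = FALSE])
  out <- rec
  out$data <- rec$data - matrix(ref, nrow = nrow(rec$data),
                                ncol = ncol(rec$data), byrow = TRUE)
  out$reference_labels <- as.character(ref_labels)
  out
}

# Odd (point-reflected) edge extension followed by a forward and a reverse
# pass of the same IIR filter; the extension length grows with the filter's
# time constant so start-up transients decay before the retained segment.
zero_phase_iir <- function(ba, x, fs, cutoff, order) {
  n <- length(x)
  pad <- min(n - 1L, max(3L * (order + 1L), as.integer(ceiling(6 * fs / cutoff))))
  xe <- c(2 * x[1] - x[seq(pad + 1L, 2L)], x,
          2 * x[n] - x[seq(n - 1L, n - pad)])
  y <- signal::filter(ba, xe)
  y <- rev(as.numeric(signal::filter(ba, rev(y))))
  y[seq(pad + 1L, pad + n)]
}

#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter and applies it forward and then in reverse
#' (doubling the effective order and cancelling the phase shift), with odd
#' edge extension to suppress start-up transients.  Output length equals
#' input length.
#'
#' @param x numeric vector (one channel / one time series).
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; must lie strictly below Nyquist.
#' @param order filter order of a single pass (the forward-reverse
#'   application doubles it).
#' @param kind `"lowpass"` or `"highpass"`.
#' @return The filtered series, same length as `x`.
#' @export
butterworth_zero_phase <- function(x, fs, cutoff, order = 6L,
                                   kind = c("lowpass", "highpass")) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf("`cutoff` (%g Hz) must lie in (0, Nyquist = %g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  }
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  ba <- signal::butter(order, cutoff / (fs / 2),
                       type = if (kind == "lowpass") "low" else "high")
  zero_phase_iir(ba, x, fs, cutoff, order)
}

# Magnitude of the analytic signal (frequency-domain Hilbert transform).
analytic_magnitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Amplitude-envelope extraction from a speech waveform
#'
#' Band-pass filters the waveform (default 80--2800 Hz), takes the magnitude
#' of the analytic signal (Hilbert transform), low-pass filters the result
#' with a zero-phase anti-alias filter (cutoff `0.4 * fs_out`, order 4) and
#' resamples it to `fs_out`.
#'
#' @param audio numeric waveform.
#' @param fs_audio waveform sampling rate in Hz; must exceed twice the upper
#'   band edge.
#' @param band numeric length-2: pass band in Hz.
#' @param fs_out output sampling rate in Hz (128 Hz in the analysis).
#' @return Nonnegative envelope sampled at `fs_out`.
#' @export
extract_envelope <- function(audio, fs_audio, band = c(80, 2800),
                             fs_out = 128) {
  if (any(band <= 0) || band[2] >= fs_audio / 2 || band[1] >= band[2]) {
    stop(sprintf("`band` (%g-%g Hz) must lie within (0, Nyquist = %g Hz)",
                 band[1], band[2], fs_audio / 2), call. = FALSE)
  }
  x <- butterworth_zero_phase(audio, fs_audio, band[1], order = 4L, kind = "highpass")
  x <- butterworth_zero_phase(x, fs_audio, band[2], order = 4L, kind = "lowpass")
  env <- analytic_magnitude(x)
  env <- butterworth_zero_phase(env, fs_audio, 0.4 * fs_out, order = 4L,
                                kind = "lowpass")
  env <- resample_series(env, fs_audio, fs_out)
  pmax(env, 0)
}

#' Resample a series to a new rate
#'
#' Polyphase resampling by a rational factor (after any anti-alias filtering
#' the caller has applied); rates need not be integer multiples.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return The resampled series, length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_series <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  frac <- rational_approx(fs_out / fs_in)
  y <- as.numeric(signal::resample(x, frac[1], frac[2]))
  n_out <- round(length(x) * fs_out / fs_in)
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

# Smallest p/q with |p/q - r| < tol (continued fractions).
rational_approx <- function(r, tol = 1e-9) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  val <- r
  for (i in 1:64) {
    a <- floor(val)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (abs(p / q - r) < tol * r || val == a) return(c(p, q))
    val <- 1 / (val - a)
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
  }
  c(p, q)
}

#' Split a recording into stimulus-aligned epochs
#'
#' Cuts the continuous recording at the given stimulus-onset samples, pairs
#' each epoch with its per-trial stimulus features, drops the first
#' `trim` seconds of both streams (so that modeled responses do not primarily
#' reflect stimulus onset), and truncates each pair to the shorter of the two
#' streams.
#'
#' @param rec an [eeg_recording()]; its `fs` must match the features'.
#' @param features list of [stimulus_features()], one per onset.
#' @param onsets strictly increasing stimulus-onset sample indices (1-based).
#' @param trim seconds removed from the start of every epoch (default 0.5).
#' @return An object of class `epoch_set`: a list with `epochs` (each a list
#'   with elements `eeg` (channels x samples), `pitch`, `envelope`),
#'   `fs`, `channel_labels`, and `onset_trim`.
#' @export
align_epochs <- function(rec, features, onsets, trim = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(features) != length(onsets)) {
    stop("need one stimulus_features per onset", call. = FALSE)
  }
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("`onsets` must be strictly increasing", call. = FALSE)
  }
  n_samp <- ncol(rec$data)
  if (any(onsets < 1L) || any(onsets > n_samp)) {
    stop("`onsets` must lie within the recording", call. = FALSE)
  }
  if (trim < 0) stop("`trim` must be >= 0", call. = FALSE)
  fs <- rec$fs
  trim_n <- round(trim * fs)
  epochs <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    f <- features[[i]]
    if (!isTRUE(all.equal(f$fs, fs))) {
      stop("feature sampling rate does not match the recording", call. = FALSE)
    }
    n_feat <- length(f$pitch)
    n_eeg <- n_samp - onsets[i] + 1L
    if (abs(n_feat - n_eeg) > fs && n_eeg < n_feat) {
      stop(sprintf(
        "epoch %d: EEG (%d samples) and features (%d samples) differ by more than 1 s; check onset alignment",
        i, n_eeg, n_feat), call. = FALSE)
    }
    n_use <- min(n_feat, n_eeg)
    keep <- seq(trim_n + 1L, n_use)
    epochs[[i]] <- list(
      eeg = rec$data[, onsets[i] + keep - 1L, drop = FALSE],
      pitch = f$pitch[keep],
      envelope = f$envelope[keep],
      trial_id = f$trial_id)
  }
  structure(list(epochs = epochs, fs = fs,
                 channel_labels = rec$channel_labels,
                 onset_trim = trim),
            class = "epoch_set")
}

#' Assemble an epoch set from already-cut trials
#'
#' Convenience constructor used when EEG arrives pre-epoched (e.g. from the
#' synthetic forward model): applies the onset trim and length matching of
#' [align_epochs()] to per-trial (EEG, features) pairs.
#'
#' @param eeg_trials list of channels x samples matrices (or
#'   [eeg_recording()]s), one per trial.
#' @param features list of [stimulus_features()], one per trial.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel labels shared by all trials.
#' @param trim seconds removed from the start of every epoch.
#' @return An `epoch_set`, as for [align_epochs()].
#' @export
epoch_set <- function(eeg_trials, features, fs, channel_labels, trim = 0.5) {
  stopifnot(length(eeg_trials) == length(features))
  trim_n <- round(trim * fs)
  epochs <- vector("list", length(eeg_trials))
  for (i in seq_along(eeg_trials)) {
    e <- eeg_trials[[i]]
    if (inherits(e, "eeg_recording")) e <- e$data
    f <- features[[i]]
    n_use <- min(ncol(e), length(f$pitch))
    keep <- seq(trim_n + 1L, n_use)
    epochs[[i]] <- list(eeg = e[, keep, drop = FALSE],
                        pitch = f$pitch[keep],
                        envelope = f$envelope[keep],
                        trial_id = f$trial_id)
  }
  structure(list(epochs = epochs, fs = fs,
                 channel_labels = as.character(channel_labels),
                 onset_trim = trim),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs, %d channels @ %g Hz, onset trim %g s\n",
              length(x$epochs), length(x$channel_labels), x$fs, x$onset_trim))
  invisible(x)
}

#' Z-score a vector
#'
#' @param x numeric vector.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x) (x - mean(x)) / stats::sd(x)
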