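#' Ground-truth description of one simulated participant
#'
#' The generative link between brain and behavior is carried by the pitch
#' gain `g`: it scales the early component of the participant's pitch TRF
#' kernel, and in a linked cohort it also (noisily) determines the
#' participant's behavioral pitch weights.
#'
#' @param id participant identifier.
#' @param pitch_gain positive scalar `g` multiplying the early pitch-kernel
#'   component.
#' @param beta_pitch_true,beta_dur_true named numeric vectors of true
#'   logistic slopes (logit units per morph step) per task.
#' @param noise_sd EEG pink-noise amplitude (same units as the simulated
#'   signal).
#' @param seed RNG seed for everything drawn for this participant.
#' @return Object of class `subject_spec`.
#' @export
subject_spec <- function(id, pitch_gain, beta_pitch_true, beta_dur_true,
                         noise_sd, seed) {
  stopifnot(pitch_gain > 0, noise_sd > 0)
  structure(list(id = id, pitch_gain = pitch_gain,
                 beta_pitch_true = beta_pitch_true,
                 beta_dur_true = beta_dur_true,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "subject_spec")
}

# Compact asymmetric bump t^a (1-t)^b on [t0, t1] ms, peak at
# t0 + (t1-t0) * a/(a+b), max 1, zero outside.
bump_kernel <- function(lag_ms, t0, t1, a, b) {
  u <- (lag_ms - t0) / (t1 - t0)
  k <- ifelse(u > 0 & u < 1, u^a * (1 - u)^b, 0)
  k / max(k)
}

#' Ground-truth TRF kernels for the forward model
#'
#' Gamma-like compactly supported bumps: an envelope kernel, an early pitch
#' component peaking near 70 ms (support 0--100 ms) whose amplitude is
#' scaled per participant by the pitch gain `g`, and a late pitch component
#' peaking near 170 ms (support 120--250 ms) shared by everyone.
#'
#' @param fs sampling rate in Hz.
#' @param max_lag_ms kernel support length in ms.
#' @return Object of class `kernel_spec`: `lag_ms`, `lags` (samples),
#'   `K_env`, `K_pitch_early`, `K_pitch_late`.
#' @export
kernel_spec <- function(fs = 128, max_lag_ms = 250) {
  lags <- 0:round(max_lag_ms * fs / 1000)
  lag_ms <- lags / fs * 1000
  structure(list(
    lag_ms = lag_ms, lags = lags, fs = fs,
    K_env = 0.8 * bump_kernel(lag_ms, 0, 180, 4, 4),         # peak 90 ms
    K_pitch_early = bump_kernel(lag_ms, 0, 100, 7, 3),       # peak 70 ms
    K_pitch_late = 0.7 * bump_kernel(lag_ms, 120, 250, 5, 8) # peak 170 ms
  ), class = "kernel_spec")
}

# Approximate 2-D scalp positions (x = left-right, y = posterior-anterior)
# for the 32-channel 10-20 montage used throughout.
montage_32 <- function() {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    AF3 = c(-0.35, 0.75), AF4 = c(0.35, 0.75),
    F7 = c(-0.81, 0.59), F3 = c(-0.42, 0.52), Fz = c(0, 0.5),
    F4 = c(0.42, 0.52), F8 = c(0.81, 0.59),
    FC5 = c(-0.69, 0.27), FC1 = c(-0.23, 0.26), FC2 = c(0.23, 0.26),
    FC6 = c(0.69, 0.27),
    T7 = c(-1, 0), C3 = c(-0.5, 0), Cz = c(0, 0), C4 = c(0.5, 0),
    T8 = c(1, 0),
    CP5 = c(-0.69, -0.27), CP1 = c(-0.23, -0.26), CP2 = c(0.23, -0.26),
    CP6 = c(0.69, -0.27),
    P7 = c(-0.81, -0.59), P3 = c(-0.42, -0.52), Pz = c(0, -0.5),
    P4 = c(0.42, -0.52), P8 = c(0.81, -0.59),
    PO3 = c(-0.35, -0.75), PO4 = c(0.35, -0.75),
    O1 = c(-0.31, -0.95), Oz = c(0, -1), O2 = c(0.31, -0.95))
  colnames(pos) <- c("x", "y")
  pos
}

#' Frontocentral scalp topography for the forward model
#'
#' Per-channel gains in `[0, 1]` over the 32-channel 10-20 montage, maximal
#' at frontocentral sites (a Gaussian falloff centered between Fz and Cz,
#' where speech-tracking responses are typically largest).
#'
#' @param sigma spatial spread of the gain falloff (montage units).
#' @return Object of class `topography_spec`: named `gains` vector and
#'   `channel_labels`.
#' @export
topography_spec <- function(sigma = 0.55) {
  pos <- montage_32()
  center <- c(0, 0.26)  # frontocentral, between Fz and Cz
  d2 <- (pos[, "x"] - center[1])^2 + (pos[, "y"] - center[2])^2
  gains <- exp(-d2 / (2 * sigma^2))
  structure(list(gains = gains, channel_labels = rownames(pos)),
            class = "topography_spec")
}

#' Generate synthetic per-trial stimulus features
#'
#' The pitch contour is z-scored low-pass-filtered Gaussian noise (default
#' smoothness 8 Hz, the time scale of natural pitch movement); the envelope
#' is a rectified, mostly positive low-pass noise process.  A target
#' pitch-envelope correlation can be requested via latent mixing (honored
#' approximately; exact at 0).
#'
#' @param duration_s trial duration in seconds.
#' @param fs sampling rate in Hz.
#' @param smoothness_hz low-pass cutoff shaping both features; must lie
#'   below Nyquist.
#' @param seed RNG seed (bit-identical output for equal seeds).
#' @param pitch_env_cor target correlation between pitch and the envelope's
#'   latent fluctuation.
#' @param trial_id identifier.
#' @return A [stimulus_features()].
#' @export
make_stimulus_features <- function(duration_s, fs = 128, smoothness_hz = 8,
                                   seed = 1L, pitch_env_cor = 0,
                                   trial_id = NA_character_) {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (smoothness_hz >= fs / 2) {
    stop(sprintf("`smoothness_hz` (%g) must be below Nyquist (%g Hz)",
                 smoothness_hz, fs / 2), call. = FALSE)
  }
  n <- round(duration_s * fs)
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  pitch <- butterworth_zero_phase(z1, fs, smoothness_hz, order = 4L, "lowpass")
  pitch <- zscore(pitch)
  latent <- pitch_env_cor * z1 + sqrt(1 - pitch_env_cor^2) * z2
  env_fluct <- butterworth_zero_phase(latent, fs, smoothness_hz, order = 4L,
                                      "lowpass")
  env_fluct <- zscore(env_fluct)
  envelope <- pmax(0, 1 + 0.45 * env_fluct)
  stimulus_features(pitch, envelope, fs = fs, trial_id = trial_id)
}

# 1/f ("pink") noise with unit SD, via spectral shaping of white noise.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

# Causal convolution of x with kernel k (k[1] applies at lag 0).
causal_conv <- function(x, k) {
  n <- length(x)
  y <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  y
}

#' Forward model: synthesize EEG epochs from stimulus features
#'
#' Each channel is a topography-scaled sum of the envelope and pitch kernel
#' responses plus pink (1/f) instrument-and-brain background noise:
#' `y_c(t) = gain_c * [conv(env_z, K_env) + conv(pitch, K_late + g * K_early)]
#'  + noise_sd * pink(t)`.
#' The envelope enters z-scored (as in the analysis), convolution is causal
#' on the kernels' stated support, and all randomness derives from the
#' participant's seed.
#'
#' @param subject a [subject_spec()].
#' @param kernels a [kernel_spec()].
#' @param topo a [topography_spec()].
#' @param features list of [stimulus_features()], one per trial.
#' @return List of [eeg_recording()] epochs (one per trial).
#' @export
synthesize_eeg <- function(subject, kernels, topo, features) {
  stopifnot(inherits(subject, "subject_spec"),
            inherits(kernels, "kernel_spec"),
            inherits(topo, "topography_spec"))
  set.seed(subject$seed)
  k_pitch <- kernels$K_pitch_late + subject$pitch_gain * kernels$K_pitch_early
  n_ch <- length(topo$gains)
  lapply(features, function(f) {
    stopifnot(isTRUE(all.equal(f$fs, kernels$fs)))
    sig <- causal_conv(zscore(f$envelope), kernels$K_env) +
      causal_conv(f$pitch, k_pitch)
    n <- length(sig)
    data <- matrix(0, n_ch, n)
    for (c in seq_len(n_ch)) {
      data[c, ] <- topo$gains[c] * sig + subject$noise_sd * pink_noise(n)
    }
    eeg_recording(data, fs = f$fs, channel_labels = topo$channel_labels,
                  reference_labels = "average-ears")
  })
}

#' Simulate one participant-task block of categorization trials
#'
#' The 4 x 4 pitch x duration morph grid is presented `n_reps` times
#' (16 trials per block, 160 trials at the standard 10 repetitions) and
#' binary responses are drawn from
#' `P(response = 1) = logistic(b0 + bp * (P - 2.5) + bd * (D - 2.5))`,
#' with levels centered at 2.5 in the simulator so the intercept stays
#' interpretable (the fitting side uses raw 1-4 coding).
#'
#' @param subject a [subject_spec()].
#' @param task task name; selects the subject's true slopes.
#' @param n_reps repetitions of the 16-cell grid.
#' @param b0 true intercept on the centered scale.
#' @return Trial table data frame: `participant`, `task`, `block`,
#'   `pitch_level`, `duration_level`, `response`.
#' @export
simulate_categorization <- function(subject, task, n_reps = 10L, b0 = 0) {
  stopifnot(n_reps >= 1L)
  bp <- subject$beta_pitch_true[[task]]
  bd <- subject$beta_dur_true[[task]]
  grid <- expand.grid(pitch_level = 1:4, duration_level = 1:4)
  tab <- grid[rep(seq_len(16L), n_reps), ]
  tab$block <- rep(seq_len(n_reps), each = 16L)
  p1 <- stats::plogis(b0 + bp * (tab$pitch_level - 2.5) +
                        bd * (tab$duration_level - 2.5))
  # task-specific stream derived from the participant seed
  set.seed(subject$seed + match(task, c("emphasis", "stress", "boundary")))
  tab$response <- stats::rbinom(nrow(tab), 1L, p1)
  data.frame(participant = subject$id, task = task,
             block = tab$block, pitch_level = tab$pitch_level,
             duration_level = tab$duration_level, response = tab$response,
             row.names = NULL)
}

#' Simulate a linked cohort with full ground truth
#'
#' Draws per-participant pitch gains `g` (lognormal) and builds behavioral
#' slopes so that pitch weights for the emphasis and stress tasks follow
#' `a + link_strength * standardize(log g) + noise`, while boundary pitch
#' weights and all duration weights are independent of `g` (the boundary
#' task mirrors the null: pitch tracking is not expected to predict its
#' weights).  Also generates the shared stimulus features and all trial
#' tables, and records every drawn value in a manifest.
#'
#' @param n cohort size (>= 10).
#' @param link_strength slope of the `g` to pitch-weight link (logit units
#'   per SD of `log g`); 0 gives a null cohort.
#' @param seed master seed; all participant seeds derive from it.
#' @param n_trials EEG trials per participant.
#' @param duration_s duration of each EEG trial in seconds.
#' @param n_reps behavioral repetitions of the 16-cell grid per task.
#' @param noise_sd_mean median EEG noise amplitude (participants vary
#'   around it lognormally).
#' @param beta_noise_sd SD of the residual scatter on linked pitch weights.
#' @param fs sampling rate in Hz.
#' @return List of class `cohort`: `subjects` (list of [subject_spec()]),
#'   `features` (shared stimulus features), `trials` (all trial tables,
#'   one data frame), `kernels`, `topo`, and `manifest` (data frame of all
#'   ground-truth values).
#' @export
make_cohort <- function(n = 60L, link_strength = 0.5, seed = 1L,
                        n_trials = 10L, duration_s = 60, n_reps = 10L,
                        noise_sd_mean = 24, beta_noise_sd = 0.25, fs = 128) {
  stopifnot(n >= 10L)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 10L, n)
  feat_seeds <- sample.int(2^31 - 10L, n_trials)
  g <- stats::rlnorm(n, meanlog = 0, sdlog = 0.4)
  zg <- zscore(log(g))
  tasks <- c("emphasis", "stress", "boundary")
  bp <- cbind(
    emphasis = 1.0 + link_strength * zg + stats::rnorm(n, 0, beta_noise_sd),
    stress = 1.0 + link_strength * zg + stats::rnorm(n, 0, beta_noise_sd),
    boundary = 0.6 + stats::rnorm(n, 0, sqrt(link_strength^2 + beta_noise_sd^2)))
  bd <- cbind(
    emphasis = stats::rnorm(n, 0.7, 0.3),
    stress = stats::rnorm(n, 0.7, 0.3),
    boundary = stats::rnorm(n, 1.2, 0.3))
  noise_sd <- stats::rlnorm(n, meanlog = log(noise_sd_mean), sdlog = 0.15)
  subjects <- lapply(seq_len(n), function(i) {
    subject_spec(id = sprintf("S%03d", i), pitch_gain = g[i],
                 beta_pitch_true = bp[i, ], beta_dur_true = bd[i, ],
                 noise_sd = noise_sd[i], seed = sub_seeds[i])
  })
  features <- lapply(seq_len(n_trials), function(t) {
    make_stimulus_features(duration_s, fs = fs, seed = feat_seeds[t],
                           trial_id = sprintf("trial_%02d", t))
  })
  trials <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(tasks, function(tk) {
      simulate_categorization(s, tk, n_reps = n_reps)
    }))
  }))
  manifest <- data.frame(
    participant = vapply(subjects, `[[`, character(1), "id"),
    pitch_gain = g, noise_sd = noise_sd, seed = sub_seeds,
    beta_pitch_emphasis = bp[, "emphasis"],
    beta_pitch_stress = bp[, "stress"],
    beta_pitch_boundary = bp[, "boundary"],
    beta_dur_emphasis = bd[, "emphasis"],
    beta_dur_stress = bd[, "stress"],
    beta_dur_boundary = bd[, "boundary"])
  structure(list(subjects = subjects, features = features, trials = trials,
                 kernels = kernel_spec(fs = fs), topo = topography_spec(),
                 manifest = manifest,
                 params = list(n = n, link_strength = link_strength,
                               seed = seed, n_trials = n_trials,
                               duration_s = duration_s, n_reps = n_reps,
                               noise_sd_mean = noise_sd_mean,
                               beta_noise_sd = beta_noise_sd, fs = fs)),
            class = "cohort")
}
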