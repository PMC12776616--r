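#' Default pipeline configuration
#'
#' Every default matches the standard analysis settings: TRF lags -50 to
#' 350 ms with the 0-300 ms interior window, ridge penalty grid `10^0..10^3`,
#' 30 Hz low-pass (order 6) and 0.2 Hz high-pass (order 4) zero-phase
#' Butterworth filters, 0.5 s onset trim, the nine most reliable channels,
#' 1000 cluster permutations, and a 6-test FDR family (2 cues x 3 tasks).
#' Simulation settings control the synthetic cohort.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    fs = 128,
    tmin_ms = -50, tmax_ms = 350,
    window_ms = c(0, 300),
    lambdas = c(1, 10, 100, 1000),
    lowpass_hz = 30, lowpass_order = 6,
    highpass_hz = 0.2, highpass_order = 4,
    onset_trim_s = 0.5,
    k_channels = 9,
    n_perm = 1000,
    cluster_threshold = 0.05,
    alpha = 0.05,
    sd_threshold = 3,
    residualize = FALSE,
    simulate = list(n_participants = 60, link_strength = 0.5, n_trials = 10,
                    duration_s = 60, n_reps = 10, noise_sd_mean = 24,
                    beta_noise_sd = 0.25),
    seed = 1,
    out = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills unset keys from [default_config()], rejects unknown keys, and
#' checks ranges (filter cutoffs below Nyquist, analysis window within the
#' lag span, channel count, permutation count).
#'
#' @param config named list of configuration overrides (possibly empty).
#' @param n_channels number of channels the data will have (for the
#'   `k_channels` check).
#' @return The completed, checked configuration.
#' @export
validate_config <- function(config = list(), n_channels = 32L) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$simulate)) {
    unknown_sim <- setdiff(names(config$simulate), names(def$simulate))
    if (length(unknown_sim)) {
      stop("unknown config key(s): ",
           paste0("simulate$", unknown_sim, collapse = ", "), call. = FALSE)
    }
    config$simulate <- utils::modifyList(def$simulate, config$simulate)
  }
  cfg <- utils::modifyList(def, config)
  nyq <- cfg$fs / 2
  if (cfg$lowpass_hz >= nyq) {
    stop("lowpass_hz must be below Nyquist", call. = FALSE)
  }
  if (cfg$highpass_hz >= nyq || cfg$highpass_hz <= 0) {
    stop("highpass_hz must lie in (0, Nyquist)", call. = FALSE)
  }
  if (cfg$tmin_ms >= cfg$tmax_ms) {
    stop("tmin_ms must be below tmax_ms", call. = FALSE)
  }
  if (cfg$window_ms[1] < cfg$tmin_ms || cfg$window_ms[2] > cfg$tmax_ms) {
    stop("window_ms must lie within [tmin_ms, tmax_ms]", call. = FALSE)
  }
  if (cfg$k_channels > n_channels) {
    stop(sprintf("k_channels (%d) exceeds the channel count (%d)",
                 cfg$k_channels, n_channels), call. = FALSE)
  }
  if (cfg$onset_trim_s < 0) stop("onset_trim_s must be >= 0", call. = FALSE)
  if (any(diff(cfg$lambdas) <= 0) || any(cfg$lambdas <= 0)) {
    stop("lambdas must be positive and strictly increasing", call. = FALSE)
  }
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads configuration overrides from YAML, applies optional further
#' overrides (e.g. from command-line flags, which take precedence), and
#' validates the result.
#'
#' @param path YAML file of configuration keys (see [default_config()]).
#' @param overrides named list applied on top of the file's values.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  validate_config(cfg)
}

# Content hash of an R object (serialization md5), for reproducibility
# bookkeeping in reports.
content_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages: simulate a cohort with known ground truth; estimate
#' per-participant cue weights (Firth regression, compliance filter, outlier
#' flags, unambiguous-stimulus accuracy); estimate each participant's pitch
#' TRF with doubly-nested cross-validation and average weights/r over the
#' nine most reliable channels; then run the group linkage: scalar Spearman
#' correlations between neural tracking and each cue weight (6-test FDR
#' family), the averaged emphasis+stress pitch-vs-duration comparison
#' (Fisher r-to-z), and lag-resolved correlations with cluster-based
#' permutation correction for the emphasis and stress pitch weights.
#'
#' @param config list of configuration overrides for [validate_config()].
#' @param progress if `TRUE`, print per-stage progress.
#' @return A report list: `config`, `cue_weights`, `participants` (per
#'   participant: tracking r, best channels), `scalar` (correlation table
#'   with FDR), `averaged` (emphasis+stress average analysis incl. Fisher
#'   comparison), `lagwise` (per task: clusters and rho series),
#'   `accuracy` (tracking vs unambiguous accuracy), `hashes`, `ground_truth`
#'   (the simulation manifest).
#' @export
run_pipeline <- function(config = list(), progress = FALSE) {
  cfg <- validate_config(config)
  say <- function(...) if (progress) message(sprintf(...))

  sim <- cfg$simulate
  say("simulating cohort (n = %d)", sim$n_participants)
  cohort <- make_cohort(n = sim$n_participants, link_strength = sim$link_strength,
                        seed = cfg$seed, n_trials = sim$n_trials,
                        duration_s = sim$duration_s, n_reps = sim$n_reps,
                        noise_sd_mean = sim$noise_sd_mean,
                        beta_noise_sd = sim$beta_noise_sd, fs = cfg$fs)

  say("estimating cue weights")
  cw <- cue_weights(cohort$trials, sd_threshold = cfg$sd_threshold)

  say("estimating TRFs")
  lags <- lag_spec(cfg$tmin_ms, cfg$tmax_ms, fs = cfg$fs,
                   edge_window_ms = cfg$window_ms)
  n_sub <- length(cohort$subjects)
  r_avg <- numeric(n_sub)
  weights_mat <- matrix(NA_real_, n_sub, length(lags$lags))
  best_channels <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- cohort$subjects[[i]]
    eeg <- synthesize_eeg(s, cohort$kernels, cohort$topo, cohort$features)
    es <- epoch_set(eeg, cohort$features, fs = cfg$fs,
                    channel_labels = cohort$topo$channel_labels,
                    trim = cfg$onset_trim_s)
    trf <- if (cfg$residualize) {
      residualized_pitch_trf(es, lags, cfg$lambdas)
    } else {
      nested_cv_trf(es, "pitch", lags, cfg$lambdas)
    }
    sel <- select_best_channels(trf, k = cfg$k_channels)
    r_avg[i] <- sel$r_avg
    weights_mat[i, ] <- sel$weights_avg
    best_channels[[i]] <- sel$channels
    say("  participant %d/%d: r = %.3f", i, n_sub, sel$r_avg)
  }
  participants <- data.frame(participant = cohort$manifest$participant,
                             tracking_r = r_avg)

  say("group statistics")
  tasks <- c("emphasis", "stress", "boundary")
  getw <- function(task, col) {
    w <- rep(NA_real_, n_sub)
    sub <- cw[cw$task == task, ]
    m <- match(participants$participant, sub$participant)
    w <- sub[[col]][m]
    out_col <- if (col == "beta_pitch") "outlier_pitch" else "outlier_duration"
    w[!sub$included[m] | sub[[out_col]][m]] <- NA_real_
    w
  }
  scalar <- do.call(rbind, lapply(tasks, function(tk) {
    rbind(
      data.frame(task = tk, cue = "pitch",
                 with(spearman(r_avg, getw(tk, "beta_pitch")),
                      data.frame(rho = rho, p_raw = p, n = n))),
      data.frame(task = tk, cue = "duration",
                 with(spearman(r_avg, getw(tk, "beta_duration")),
                      data.frame(rho = rho, p_raw = p, n = n))))
  }))
  scalar$p_fdr <- fdr_adjust(scalar$p_raw)

  # averaged emphasis+stress weights (over available, non-outlier tasks)
  avg2 <- function(col) {
    rowMeans(cbind(getw("emphasis", col), getw("stress", col)), na.rm = TRUE)
  }
  pw <- avg2("beta_pitch"); dw <- avg2("beta_duration")
  sp_p <- spearman(r_avg, pw)
  sp_d <- spearman(r_avg, dw)
  cmp <- compare_correlations(sp_p$rho, sp_p$n, sp_d$rho, sp_d$n)
  averaged <- list(pitch = sp_p, duration = sp_d, comparison = cmp)

  lagwise <- lapply(setNames(c("emphasis", "stress"),
                             c("emphasis", "stress")), function(tk) {
    w <- getw(tk, "beta_pitch")
    ok <- is.finite(w)
    cluster_permutation(weights_mat[ok, , drop = FALSE], w[ok],
                        lag_ms = lags$lag_ms, window_ms = cfg$window_ms,
                        n_perm = cfg$n_perm,
                        cluster_threshold = cfg$cluster_threshold,
                        alpha = cfg$alpha, seed = cfg$seed + 101L)
  })

  # attention control: tracking vs unambiguous-corner accuracy
  accuracy <- do.call(rbind, lapply(tasks, function(tk) {
    sub <- cw[cw$task == tk, ]
    m <- match(participants$participant, sub$participant)
    acc <- sub$accuracy_unambiguous[m]
    acc[!sub$included[m]] <- NA
    res <- tryCatch(spearman(r_avg, acc),
                    error = function(e) list(rho = NA_real_, p = NA_real_,
                                             n = sum(is.finite(acc))))
    data.frame(task = tk, rho = res$rho, p = res$p, n = res$n)
  }))

  report <- list(
    config = cfg,
    cue_weights = cw,
    participants = cbind(participants, weights_mat),
    scalar = scalar,
    averaged = averaged,
    lagwise = lagwise,
    accuracy = accuracy,
    lag_ms = lags$lag_ms,
    ground_truth = cohort$manifest)
  report$hashes <- list(
    trials = content_hash(cohort$trials),
    cue_weights = content_hash(cw),
    trf_weights = content_hash(weights_mat),
    scalar = content_hash(scalar))

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(cfg$out, "report.json"))
  }
  report
}

#' Write a pipeline report to JSON
#'
#' Serializes the group-level results (config echo, scalar correlations,
#' averaged analysis, clusters, hashes) to a JSON file; the large
#' per-participant weight matrices are omitted.
#'
#' @param report a list from [run_pipeline()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  slim <- list(
    config = report$config,
    scalar = report$scalar,
    averaged = list(
      rho_pitch = report$averaged$pitch$rho,
      p_pitch = report$averaged$pitch$p,
      rho_duration = report$averaged$duration$rho,
      p_duration = report$averaged$duration$p,
      comparison_z = report$averaged$comparison$z,
      comparison_p = report$averaged$comparison$p),
    clusters = lapply(report$lagwise, `[[`, "clusters"),
    accuracy = report$accuracy,
    hashes = report$hashes)
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"), path)
  invisible(path)
}
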