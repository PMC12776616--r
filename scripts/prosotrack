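#!/usr/bin/env Rscript
# Thin command-line wrapper around the prosotrack R package.
#
#   prosotrack simulate  --n-subjects 60 --trials 10 --duration 60 --link 0.5
#                        --seed 7 --out DIR [--eeg-subjects 2]
#   prosotrack cueweights --trials trials.tsv --out weights.tsv
#   prosotrack trf       --epochs DIR --feature pitch|envelope|pitch_residual
#                        --tmin -50 --tmax 350 --lambdas 1,10,100,1000 --out DIR
#   prosotrack link      --trf-dir DIR --weights weights.tsv --task emphasis
#                        --window 0,300 --nperm 1000 --seed 11 --out report.json
#   prosotrack all       --config run.yaml [--seed N] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(prosotrack)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: prosotrack <simulate|cueweights|trf|link|all> [options]",
       call. = FALSE)
}
cmd <- args[1L]
rest <- args[-1L]

num_list <- function(s) as.numeric(strsplit(s, ",")[[1]])

if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--n-subjects", type = "integer", default = 60L, dest = "n"),
    make_option("--trials", type = "integer", default = 10L),
    make_option("--duration", type = "double", default = 60),
    make_option("--link", type = "double", default = 0.5),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--eeg-subjects", type = "integer", default = 2L,
                dest = "eeg_subjects"),
    make_option("--out", type = "character", default = "simdata")
  )), args = rest)
  co <- make_cohort(n = o$n, link_strength = o$link, seed = o$seed,
                    n_trials = o$trials, duration_s = o$duration)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_trials_tsv(co$trials, file.path(o$out, "trials.tsv"))
  utils::write.table(co$manifest, file.path(o$out, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(co$params, auto_unbox = TRUE, digits = NA),
             file.path(o$out, "params.json"))
  for (i in seq_len(min(o$eeg_subjects, o$n))) {
    s <- co$subjects[[i]]
    eeg <- synthesize_eeg(s, co$kernels, co$topo, co$features)
    es <- epoch_set(eeg, co$features, fs = co$params$fs,
                    channel_labels = co$topo$channel_labels, trim = 0.5)
    write_epoch_dir(es, file.path(o$out, "epochs", s$id))
  }
  cat("wrote", o$out, "\n")
} else if (cmd == "cueweights") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--trials", type = "character"),
    make_option("--out", type = "character", default = "weights.tsv")
  )), args = rest)
  cw <- cue_weights(read_trials_tsv(o$trials))
  utils::write.table(cw, o$out, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("wrote", o$out, "\n")
} else if (cmd == "trf") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--epochs", type = "character"),
    make_option("--feature", type = "character", default = "pitch"),
    make_option("--tmin", type = "double", default = -50),
    make_option("--tmax", type = "double", default = 350),
    make_option("--lambdas", type = "character", default = "1,10,100,1000"),
    make_option("--out", type = "character", default = "trf_out")
  )), args = rest)
  es <- read_epoch_dir(o$epochs)
  lags <- lag_spec(o$tmin, o$tmax, fs = es$fs)
  res <- if (o$feature == "pitch_residual") {
    residualized_pitch_trf(es, lags, num_list(o$lambdas))
  } else {
    nested_cv_trf(es, o$feature, lags, num_list(o$lambdas))
  }
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  w <- data.frame(lag_ms = res$lag_ms, edge = res$edge, res$weights)
  names(w)[-(1:2)] <- res$channel_labels
  utils::write.table(w, file.path(o$out, "weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(channel = res$channel_labels, r = res$r),
    file.path(o$out, "r.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(list(feature = res$feature,
                                   lambda_per_fold = res$lambda_per_fold),
                              auto_unbox = TRUE, digits = NA),
             file.path(o$out, "meta.json"))
  cat("wrote", o$out, "\n")
} else if (cmd == "link") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--trf-dir", type = "character", dest = "trf_dir",
                help = "directory of per-participant TRF outputs"),
    make_option("--weights", type = "character"),
    make_option("--task", type = "character", default = "emphasis"),
    make_option("--k", type = "integer", default = 9L),
    make_option("--window", type = "character", default = "0,300"),
    make_option("--nperm", type = "integer", default = 1000L),
    make_option("--seed", type = "integer", default = 11L),
    make_option("--out", type = "character", default = "report.json")
  )), args = rest)
  cw <- utils::read.delim(o$weights)
  cw <- cw[cw$task == o$task, ]
  ids <- sort(list.dirs(o$trf_dir, recursive = FALSE, full.names = FALSE))
  lagw <- NULL; r_avg <- numeric(0)
  for (id in ids) {
    wt <- utils::read.delim(file.path(o$trf_dir, id, "weights.tsv"))
    rt <- utils::read.delim(file.path(o$trf_dir, id, "r.tsv"))
    best <- order(rt$r, decreasing = TRUE)[seq_len(o$k)]
    lagw <- rbind(lagw, rowMeans(as.matrix(wt[, -(1:2)])[, best]))
    r_avg <- c(r_avg, mean(rt$r[best]))
  }
  lag_ms <- utils::read.delim(file.path(o$trf_dir, ids[1],
                                        "weights.tsv"))$lag_ms
  behavior <- cw$beta_pitch[match(ids, cw$participant)]
  win <- num_list(o$window)
  sp <- spearman(r_avg, behavior)
  cl <- cluster_permutation(lagw, behavior, lag_ms, window_ms = win,
                            n_perm = o$nperm, seed = o$seed)
  writeLines(jsonlite::toJSON(list(
    task = o$task, rho = sp$rho, p = sp$p, n = sp$n,
    clusters = cl$clusters), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"), o$out)
  cat("wrote", o$out, "\n")
} else if (cmd == "all") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--config", type = "character", default = NULL),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--out", type = "character", default = NULL)
  )), args = rest)
  overrides <- list()
  if (!is.null(o$seed)) overrides$seed <- o$seed
  if (!is.null(o$out)) overrides$out <- o$out
  cfg <- read_run_config(o$config, overrides)
  report <- run_pipeline(cfg, progress = TRUE)
  if (is.null(cfg$out)) {
    write_report_json(report, "report.json")
    cat("wrote report.json\n")
  }
} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
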