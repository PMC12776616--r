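# Shared fixture builders; everything is generated in code, no stored data.

# Full 4x4 morph grid repeated n_reps times with responses from a logistic
# rule (deterministic if probs are 0/1).
make_trial_table <- function(bp, bd, b0 = 0, n_reps = 10L, seed = 1L,
                             participant = "P1", task = "emphasis") {
  grid <- expand.grid(pitch_level = 1:4, duration_level = 1:4)
  tab <- grid[rep(seq_len(16L), n_reps), ]
  set.seed(seed)
  p1 <- plogis(b0 + bp * (tab$pitch_level - 2.5) + bd * (tab$duration_level - 2.5))
  data.frame(participant = participant, task = task,
             pitch_level = tab$pitch_level,
             duration_level = tab$duration_level,
             response = rbinom(nrow(tab), 1L, p1), row.names = NULL)
}

# Small epoch set built from a known forward model: EEG = conv(pitch, k) on
# each channel (scaled by ch_gains) + white noise.
make_known_epochs <- function(n_ep = 4L, n_s = 600L, fs = 128,
                              kernel = NULL, ch_gains = c(1, 0.8, 0.5),
                              noise = 0, seed = 1L, trim = 0) {
  if (is.null(kernel)) {
    kernel <- exp(-((0:24) - 9)^2 / 18)  # smooth bump peaking at lag 9
  }
  set.seed(seed)
  feats <- list(); eegs <- list()
  for (i in seq_len(n_ep)) {
    pitch <- as.numeric(scale(stats::filter(rnorm(n_s + 50), rep(1, 5),
                                            sides = 1)[-(1:50)]))
    env <- pmax(0, 1 + 0.4 * as.numeric(scale(stats::filter(
      rnorm(n_s + 50), rep(1, 7), sides = 1)[-(1:50)])))
    sig <- stats::convolve(pitch, rev(kernel), type = "open")[seq_len(n_s)]
    eeg <- t(sapply(ch_gains, function(g) g * sig + noise * rnorm(n_s)))
    feats[[i]] <- stimulus_features(pitch, env, fs = fs,
                                    trial_id = sprintf("t%d", i))
    eegs[[i]] <- eeg
  }
  epoch_set(eegs, feats, fs = fs,
            channel_labels = paste0("ch", seq_along(ch_gains)), trim = trim)
}

# Grid-search oracle for the Jeffreys-penalized logistic likelihood on a
# 2-column design [1, x]: coarse grid refined around the argmax.
firth_grid_oracle <- function(x, y, rounds = 4L, span0 = 12, k = 81L) {
  X <- cbind(1, x)
  pll <- function(b0, b1) {
    eta <- b0 + b1 * x
    pi <- plogis(eta)
    I <- crossprod(X * (pi * (1 - pi)), X)
    sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(determinant(I)$modulus)
  }
  c0 <- 0; c1 <- 0; span <- span0
  for (r in seq_len(rounds)) {
    g <- expand.grid(b0 = seq(c0 - span, c0 + span, length.out = k),
                     b1 = seq(c1 - span, c1 + span, length.out = k))
    v <- mapply(pll, g$b0, g$b1)
    best <- g[which.max(v), ]
    c0 <- best$b0; c1 <- best$b1
    span <- 2.5 * (2 * span / (k - 1))  # shrink around the incumbent
  }
  c(b0 = c0, b1 = c1)
}
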