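#' Lag specification for TRF estimation
#'
#' Converts a lag window in milliseconds to the consecutive integer sample
#' lags used in the lagged design matrix.  Positive lags mean the stimulus
#' precedes the EEG.  Lags outside 0--300 ms are flagged as edge lags so
#' downstream analyses can exclude them (model weights there carry
#' artifactual edge effects).
#'
#' @param tmin_ms,tmax_ms lag window in ms (defaults -50 and 350).
#' @param fs sampling rate in Hz.
#' @param edge_window_ms interior window in ms; lags outside it are flagged
#'   as edges.
#' @return List of class `lag_spec`: `lags` (integer sample lags,
#'   `round(tmin_ms * fs / 1000)` to `round(tmax_ms * fs / 1000)`), `lag_ms`,
#'   `edge` (logical), `fs`.
#' @export
lag_spec <- function(tmin_ms = -50, tmax_ms = 350, fs = 128,
                     edge_window_ms = c(0, 300)) {
  if (tmin_ms >= tmax_ms) stop("tmin_ms must be < tmax_ms", call. = FALSE)
  lags <- seq.int(round(tmin_ms * fs / 1000), round(tmax_ms * fs / 1000))
  lag_ms <- lags / fs * 1000
  structure(list(lags = lags, lag_ms = lag_ms,
                 edge = lag_ms < edge_window_ms[1] | lag_ms > edge_window_ms[2],
                 fs = fs),
            class = "lag_spec")
}

#' Build a lagged design matrix
#'
#' Row `t`, lag column `j` holds `feature[t - lag_j]`, zero-padded where the
#' index falls outside the series; columns are in ascending lag order with a
#' leading all-ones intercept column.
#'
#' @param feature numeric time series.
#' @param lags a [lag_spec()] or an integer vector of sample lags.
#' @return Matrix with `length(feature)` rows and `length(lags) + 1` columns.
#' @export
build_lag_matrix <- function(feature, lags) {
  if (inherits(lags, "lag_spec")) lags <- lags$lags
  n <- length(feature)
  if (n <= length(lags)) {
    stop("series must be longer than the number of lags", call. = FALSE)
  }
  X <- matrix(0, n, length(lags) + 1L)
  X[, 1L] <- 1
  for (j in seq_along(lags)) {
    lag <- lags[j]
    src <- seq_len(n) - lag
    ok <- src >= 1L & src <= n
    X[ok, j + 1L] <- feature[src[ok]]
  }
  colnames(X) <- c("intercept", paste0("lag", lags))
  X
}

# Cholesky ridge solve of (S + lambda*M) W = C with the intercept
# (first row/column) unpenalized.
ridge_solve <- function(S, C, lambda) {
  A <- S
  if (lambda > 0) {
    idx <- seq(2L, nrow(S))
    diag(A)[idx] <- diag(A)[idx] + lambda
  }
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    stop("normal equations are singular; use lambda > 0 with collinear predictors",
         call. = FALSE)
  }
  backsolve(R, forwardsolve(t(R), C))
}

#' Ridge regression of multi-channel responses on a lagged design
#'
#' Solves, per channel, `w = (X'X + lambda * M)^-1 X'Y` where `M` is the
#' identity with a zero at the intercept position (the intercept is not
#' penalized), via a Cholesky decomposition of the regularized normal
#' equations.
#'
#' @param X design matrix with a leading intercept column
#'   (see [build_lag_matrix()]).
#' @param Y samples x channels response matrix (a vector is treated as one
#'   channel).
#' @param lambda ridge penalty, `>= 0`.
#' @return List with `weights` (lags x channels, intercept row removed) and
#'   `intercept` (per channel).
#' @export
ridge_fit <- function(X, Y, lambda) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  Y <- as.matrix(Y)
  B <- ridge_solve(crossprod(X), crossprod(X, Y), lambda)
  list(weights = B[-1L, , drop = FALSE], intercept = B[1L, ])
}

# Per-epoch sufficient statistics for fast leave-one-out refits and
# prediction scoring: S = X'X, C = X'Y, xs = colSums(X), ys = colSums(Y),
# yy = colSums(Y^2), n = samples.  Prediction-vs-actual Pearson
# correlations only need these, never the raw series, so the inner
# cross-validation cost is independent of epoch length.
trf_prepare <- function(epochs, feature_name, lags) {
  lapply(epochs$epochs, function(ep) {
    X <- build_lag_matrix(ep[[feature_name]], lags)
    Y <- t(ep$eeg)
    list(S = crossprod(X), C = crossprod(X, Y), xs = colSums(X),
         ys = colSums(Y), yy = colSums(Y^2), n = nrow(X))
  })
}

# Per-channel Pearson r between X_e B and Y_e from epoch statistics:
# cov = B'C - n m_p m_y, var_p = diag(B'SB) - n m_p^2, var_y = yy - n m_y^2.
stat_pred_cor <- function(st, B) {
  n <- st$n
  mp <- drop(crossprod(B, st$xs)) / n
  my <- st$ys / n
  varp <- colSums(B * (st$S %*% B)) - n * mp^2
  vary <- st$yy - n * my^2
  cv <- colSums(B * st$C) - n * mp * my
  den <- sqrt(pmax(varp, 0) * pmax(vary, 0))
  r <- ifelse(den > 0, cv / den, 0)
  pmin(pmax(r, -1), 1)
}

# Inner leave-one-out lambda selection over training epochs: scores each
# candidate by mean Pearson r (channels, then folds); smallest lambda on
# ties.
inner_select_lambda <- function(prep, train_idx, lambdas) {
  S_tr <- Reduce(`+`, lapply(prep[train_idx], `[[`, "S"))
  C_tr <- Reduce(`+`, lapply(prep[train_idx], `[[`, "C"))
  score <- matrix(NA_real_, length(train_idx), length(lambdas))
  for (ii in seq_along(train_idx)) {
    i <- train_idx[ii]
    S2 <- S_tr - prep[[i]]$S
    C2 <- C_tr - prep[[i]]$C
    for (li in seq_along(lambdas)) {
      B <- ridge_solve(S2, C2, lambdas[li])
      score[ii, li] <- mean(stat_pred_cor(prep[[i]], B))
    }
  }
  mean_score <- colMeans(score)
  lambdas[which.max(mean_score)]
}

#' TRF estimation with doubly-nested leave-one-out cross-validation
#'
#' Outer loop: each epoch serves once as the test epoch.  Inner loop:
#' leave-one-out over the remaining epochs scores each candidate ridge
#' penalty by the mean Pearson correlation between predicted and actual EEG
#' (averaged over channels, then inner folds); ties go to the smaller
#' penalty.  The model is then retrained on all training epochs at the
#' selected penalty and evaluated on the held-out epoch.  Reported weights
#' and per-channel correlations are averages over the outer folds.
#'
#' @param epochs an `epoch_set` with at least 3 epochs (onset-trimmed
#'   samples are already excluded by [align_epochs()] / [epoch_set()]).
#' @param feature_name `"pitch"` or `"envelope"`.
#' @param lags a [lag_spec()].
#' @param lambdas candidate ridge penalties, ascending (default
#'   `10^(0:3)`).
#' @return Object of class `trf_result`: `weights` (lag x channel,
#'   fold-averaged), `intercept`, `r` (per-channel fold-averaged test
#'   correlation), `lambda_per_fold`, `lag_ms`, `edge`, `channel_labels`,
#'   `feature`.
#' @export
nested_cv_trf <- function(epochs, feature_name = "pitch",
                          lags = lag_spec(fs = epochs$fs),
                          lambdas = 10^(0:3)) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- length(epochs$epochs)
  if (n_ep < 3L) {
    stop("nested cross-validation needs at least 3 epochs (no inner split possible)",
         call. = FALSE)
  }
  prep <- trf_prepare(epochs, feature_name, lags)
  trf_from_prep(prep, epochs, feature_name, lags, lambdas)
}

# Shared engine: nested CV given precomputed per-epoch statistics.
trf_from_prep <- function(prep, epochs, feature_name, lags, lambdas) {
  n_ep <- length(prep)
  n_ch <- ncol(prep[[1L]]$C)
  lambda_per_fold <- numeric(n_ep)
  r_folds <- matrix(NA_real_, n_ep, n_ch)
  W_sum <- matrix(0, length(lags$lags), n_ch)
  b0_sum <- numeric(n_ch)
  for (o in seq_len(n_ep)) {
    train_idx <- setdiff(seq_len(n_ep), o)
    best <- inner_select_lambda(prep, train_idx, lambdas)
    lambda_per_fold[o] <- best
    S_tr <- Reduce(`+`, lapply(prep[train_idx], `[[`, "S"))
    C_tr <- Reduce(`+`, lapply(prep[train_idx], `[[`, "C"))
    B <- ridge_solve(S_tr, C_tr, best)
    r_folds[o, ] <- stat_pred_cor(prep[[o]], B)
    W_sum <- W_sum + B[-1L, , drop = FALSE]
    b0_sum <- b0_sum + B[1L, ]
  }
  structure(list(
    weights = W_sum / n_ep,
    intercept = b0_sum / n_ep,
    r = colMeans(r_folds),
    r_folds = r_folds,
    lambda_per_fold = lambda_per_fold,
    lag_ms = lags$lag_ms,
    edge = lags$edge,
    channel_labels = epochs$channel_labels,
    feature = feature_name), class = "trf_result")
}

#' @export
print.trf_result <- function(x, ...) {
  cat(sprintf(
    "<trf_result> feature '%s': %d lags (%g..%g ms) x %d channels, mean r = %.4f\n",
    x$feature, length(x$lag_ms), min(x$lag_ms), max(x$lag_ms),
    ncol(x$weights), mean(x$r)))
  invisible(x)
}

#' Envelope-residualized pitch TRF
#'
#' Two-stage model isolating pitch tracking beyond what the amplitude
#' envelope explains.  Within each outer fold, stage 1 fits an envelope TRF
#' on the training epochs (with its own inner-CV penalty selection); its
#' predictions are subtracted from *all* epochs' EEG to form residuals
#' (fold-specific residualization, so no test data leaks into training).
#' Stage 2 then selects the pitch-model penalty by inner leave-one-out on the
#' training residuals, trains on them, and tests on the held-out epoch's
#' residual.
#'
#' @inheritParams nested_cv_trf
#' @return A `trf_result` for the pitch model on envelope residuals, with
#'   `lambda_env_per_fold` recording the stage-1 penalties.
#' @export
residualized_pitch_trf <- function(epochs, lags = lag_spec(fs = epochs$fs),
                                   lambdas = 10^(0:3)) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- length(epochs$epochs)
  if (n_ep < 3L) {
    stop("nested cross-validation needs at least 3 epochs (no inner split possible)",
         call. = FALSE)
  }
  prep_env <- trf_prepare(epochs, "envelope", lags)
  prep_pitch <- trf_prepare(epochs, "pitch", lags)
  # pitch x envelope cross-products, needed to residualize the statistics
  Spe <- lapply(epochs$epochs, function(ep) {
    crossprod(build_lag_matrix(ep$pitch, lags),
              build_lag_matrix(ep$envelope, lags))
  })
  n_ch <- ncol(prep_env[[1L]]$C)
  lambda_per_fold <- numeric(n_ep)
  lambda_env_per_fold <- numeric(n_ep)
  r_folds <- matrix(NA_real_, n_ep, n_ch)
  W_sum <- matrix(0, length(lags$lags), n_ch)
  b0_sum <- numeric(n_ch)
  for (o in seq_len(n_ep)) {
    train_idx <- setdiff(seq_len(n_ep), o)
    # stage 1: envelope model on training epochs only
    lam_env <- inner_select_lambda(prep_env, train_idx, lambdas)
    lambda_env_per_fold[o] <- lam_env
    S_env <- Reduce(`+`, lapply(prep_env[train_idx], `[[`, "S"))
    C_env <- Reduce(`+`, lapply(prep_env[train_idx], `[[`, "C"))
    B_env <- ridge_solve(S_env, C_env, lam_env)
    # residualize every epoch's statistics with the fold's envelope model:
    # for R = Y - X_env B, X_pitch'R, colSums(R) and colSums(R^2) follow
    # algebraically from the stored cross-products
    prep_res <- lapply(seq_len(n_ep), function(i) {
      pe <- prep_env[[i]]; pp <- prep_pitch[[i]]
      list(S = pp$S,
           C = pp$C - Spe[[i]] %*% B_env,
           xs = pp$xs,
           ys = pe$ys - drop(crossprod(B_env, pe$xs)),
           yy = pe$yy - 2 * colSums(B_env * pe$C) +
             colSums(B_env * (pe$S %*% B_env)),
           n = pe$n)
    })
    # stage 2: nested pitch model on the residuals
    best <- inner_select_lambda(prep_res, train_idx, lambdas)
    lambda_per_fold[o] <- best
    S_tr <- Reduce(`+`, lapply(prep_res[train_idx], `[[`, "S"))
    C_tr <- Reduce(`+`, lapply(prep_res[train_idx], `[[`, "C"))
    B <- ridge_solve(S_tr, C_tr, best)
    r_folds[o, ] <- stat_pred_cor(prep_res[[o]], B)
    W_sum <- W_sum + B[-1L, , drop = FALSE]
    b0_sum <- b0_sum + B[1L, ]
  }
  structure(list(
    weights = W_sum / n_ep,
    intercept = b0_sum / n_ep,
    r = colMeans(r_folds),
    r_folds = r_folds,
    lambda_per_fold = lambda_per_fold,
    lambda_env_per_fold = lambda_env_per_fold,
    lag_ms = lags$lag_ms,
    edge = lags$edge,
    channel_labels = epochs$channel_labels,
    feature = "pitch_residual"), class = "trf_result")
}

#' Select the most reliable channels and average over them
#'
#' Ranks channels by fold-averaged prediction correlation and keeps the top
#' `k` (nine in the standard analysis); weights and r-values are averaged
#' over that subset for all subsequent cross-channel analyses.
#'
#' @param result a `trf_result`.
#' @param k number of channels to keep.
#' @return List: `channels` (labels, ranked), `idx`, `r_avg` (scalar),
#'   `weights_avg` (lag vector), `lag_ms`, `edge`.
#' @export
select_best_channels <- function(result, k = 9L) {
  stopifnot(inherits(result, "trf_result"))
  n_ch <- length(result$r)
  if (k > n_ch) stop("`k` exceeds the number of channels", call. = FALSE)
  idx <- order(result$r, decreasing = TRUE)[seq_len(k)]
  list(channels = result$channel_labels[idx],
       idx = idx,
       r_avg = mean(result$r[idx]),
       weights_avg = rowMeans(result$weights[, idx, drop = FALSE]),
       lag_ms = result$lag_ms,
       edge = result$edge)
}
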