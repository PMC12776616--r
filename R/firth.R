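#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det I(\beta),}
#' where \eqn{I(\beta) = X^\top W X} and \eqn{W = \mathrm{diag}(\pi(1-\pi))},
#' by Newton iterations on the hat-value-modified score
#' \eqn{U^*_j = \sum_i (y_i - \pi_i + h_i(1/2 - \pi_i)) x_{ij}} with
#' step-halving whenever the penalized likelihood would decrease.  The
#' penalty keeps estimates finite even under complete separation, where
#' ordinary maximum likelihood diverges.
#'
#' @param X numeric design matrix (include an intercept column yourself).
#' @param y 0/1 response vector.
#' @param fixed integer indices of coefficients constrained to zero (used by
#'   the penalized likelihood-ratio test); the penalty is always computed
#'   from the full design.
#' @param tol convergence tolerance on the largest free component of the
#'   modified score.
#' @param max_iter maximum Newton iterations.
#' @return List with `beta`, `pll` (penalized log-likelihood at the optimum),
#'   `iter`, `converged`, and `vcov` (inverse Fisher information at the
#'   optimum, for optional Wald inference).
#' @references Firth, D. (1993) Bias reduction of maximum likelihood
#'   estimates. Biometrika 80, 27-38.  Heinze, G. & Schemper, M. (2002)
#'   A solution to the problem of separation in logistic regression.
#'   Statistics in Medicine 21, 2409-2419.
#' @export
firth_logistic <- function(X, y, fixed = integer(0), tol = 1e-6,
                           max_iter = 50L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty design matrix", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- numeric(p)

  pll_at <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(X * w, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    ld <- determinant(info, logarithm = TRUE)
    ll + 0.5 * as.numeric(ld$modulus)
  }

  pll_old <- pll_at(beta)
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- pi * (1 - pi)
    XW <- X * w
    info <- crossprod(XW, X)
    # hat values of the weighted design: h_i = w_i x_i' I^{-1} x_i
    R <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(R)) stop("Fisher information is singular", call. = FALSE)
    h <- w * rowSums((X %*% chol2inv(R)) * X)
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    if (max(abs(score[free])) < tol) {
      converged <- TRUE
      break
    }
    delta <- numeric(p)
    delta[free] <- solve(info[free, free, drop = FALSE], score[free])
    # step-halving: never accept a step that lowers the penalized likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      pll_new <- pll_at(cand)
      if (is.finite(pll_new) && pll_new >= pll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    pll_old <- pll_at(beta)
    trace <- c(trace, pll_old)
  }
  if (!converged) {
    # final score check (max_iter reached exactly at convergence is fine)
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(X * w, X)
    h <- w * rowSums((X %*% chol2inv(chol(info))) * X)
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    if (max(abs(score[free])) < tol) converged <- TRUE
    if (!converged) {
      stop(sprintf(
        "Firth fit did not converge in %d iterations (last |score| = %.3g; penalized LL trace: %s)",
        max_iter, max(abs(score[free])),
        paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", ")),
        call. = FALSE)
    }
  }
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  info <- crossprod(X * (pi * (1 - pi)), X)
  list(beta = beta, pll = pll_old, iter = iter, converged = converged,
       vcov = chol2inv(chol(info)))
}

# Penalized likelihood-ratio p-value for coefficient j: refit with beta_j
# fixed at 0 (penalty still from the full design) and compare twice the
# penalized log-likelihood difference to chi-square with 1 df.
firth_plr_p <- function(X, y, j, full_pll, tol = 1e-6, max_iter = 50L) {
  f0 <- firth_logistic(X, y, fixed = j, tol = tol, max_iter = max_iter)
  stat <- max(0, 2 * (full_pll - f0$pll))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Per-participant cue weights by Firth regression
#'
#' Fits `logit P(response = 1) = b0 + bp * pitch_level + bd * duration_level`
#' to one participant-task block of categorization trials, with morph levels
#' entered raw as 1-4.  Coefficients are the behavioral cue weights (logit
#' units per morph step); per-coefficient p-values come from the penalized
#' likelihood-ratio test (Wald p-values optionally, behind `wald`).
#'
#' @param table data frame with columns `pitch_level`, `duration_level`
#'   (integers 1-4) and `response` (0/1); at least 16 rows.
#' @param wald if `TRUE`, also report Wald p-values (`p_pitch_wald`,
#'   `p_duration_wald`).
#' @return One-row data frame: `beta_intercept`, `beta_pitch`,
#'   `beta_duration`, `p_pitch`, `p_duration`, `n_trials`, `iter`,
#'   `converged` (and Wald columns if requested).
#' @export
firth_fit <- function(table, wald = FALSE) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("empty trial table", call. = FALSE)
  }
  need <- c("pitch_level", "duration_level", "response")
  if (!all(need %in% names(table))) {
    stop("trial table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(table$pitch_level %in% 1:4) || !all(table$duration_level %in% 1:4)) {
    stop("morph levels must be coded 1-4", call. = FALSE)
  }
  X <- cbind(intercept = 1, pitch = table$pitch_level,
             duration = table$duration_level)
  y <- table$response
  fit <- firth_logistic(X, y)
  out <- data.frame(
    beta_intercept = fit$beta[1],
    beta_pitch = fit$beta[2],
    beta_duration = fit$beta[3],
    p_pitch = firth_plr_p(X, y, 2L, fit$pll),
    p_duration = firth_plr_p(X, y, 3L, fit$pll),
    n_trials = nrow(table),
    iter = fit$iter,
    converged = fit$converged)
  if (wald) {
    se <- sqrt(diag(fit$vcov))
    out$p_pitch_wald <- 2 * stats::pnorm(-abs(fit$beta[2] / se[2]))
    out$p_duration_wald <- 2 * stats::pnorm(-abs(fit$beta[3] / se[3]))
  }
  out
}

#' Task-compliance filter
#'
#' A participant is retained only if, on every one of the three tasks, at
#' least one acoustic dimension (pitch or duration) relates significantly
#' (p < 0.05) to their responses; participants failing this on any task are
#' assumed to be responding randomly.
#'
#' @param results data frame of [firth_fit()] rows for one participant with a
#'   `task` column covering `tasks`.
#' @param tasks the tasks that must all be present.
#' @param alpha significance level of the per-task test.
#' @return `TRUE` if the participant is retained.
#' @export
compliance_filter <- function(results,
                              tasks = c("emphasis", "stress", "boundary"),
                              alpha = 0.05) {
  missing_task <- setdiff(tasks, results$task)
  if (length(missing_task)) {
    stop("missing task(s): ", paste(missing_task, collapse = ", "),
         call. = FALSE)
  }
  all(vapply(tasks, function(tk) {
    r <- results[results$task == tk, ][1, ]
    min(r$p_pitch, r$p_duration) < alpha
  }, logical(1)))
}

#' Flag anomalous significantly-negative cue weights
#'
#' A weight is flagged only when it is significantly negative (p < `alpha`
#' and estimate < 0) *and* an extreme outlier relative to the cohort
#' (more than `sd_threshold` SDs from the cohort mean).  Flagged weights are
#' excluded from that task's group analyses only; the participant's other
#' data are retained.
#'
#' @param weight the participant's cue weight for one task.
#' @param p its p-value.
#' @param cohort_weights all participants' weights for the same task/cue
#'   (length >= 3).
#' @param alpha significance level.
#' @param sd_threshold SD distance defining "extreme".
#' @return `TRUE` if the weight should be excluded.
#' @export
outlier_flag <- function(weight, p, cohort_weights, alpha = 0.05,
                         sd_threshold = 3) {
  if (length(cohort_weights) < 3L) {
    stop("need at least 3 cohort weights", call. = FALSE)
  }
  signif_neg <- is.finite(p) && p < alpha && weight < 0
  extreme <- abs(weight - mean(cohort_weights)) / stats::sd(cohort_weights) >
    sd_threshold
  isTRUE(signif_neg && extreme)
}

#' Accuracy on the unambiguous corner stimuli
#'
#' Proportion of correct responses on the two corners of the morph grid where
#' pitch and duration agree: cell (1,1) (both at the "early" endpoint;
#' correct response 0) and cell (4,4) (both "late"; correct response 1).
#' With 10 repetitions per cell the denominator is 20.
#'
#' @param table a trial table as for [firth_fit()].
#' @return Proportion correct in `[0, 1]`.
#' @export
unambiguous_accuracy <- function(table) {
  lo <- table$pitch_level == 1 & table$duration_level == 1
  hi <- table$pitch_level == 4 & table$duration_level == 4
  if (!any(lo) || !any(hi)) {
    stop("trial table lacks the unambiguous cells (1,1) and/or (4,4)",
         call. = FALSE)
  }
  correct <- sum(table$response[lo] == 0) + sum(table$response[hi] == 1)
  correct / (sum(lo) + sum(hi))
}

#' Cue-weight results for a whole cohort
#'
#' Runs [firth_fit()] per participant and task, applies the compliance filter
#' across tasks, flags outlying significantly-negative weights within each
#' task (among compliant participants), and computes unambiguous-stimulus
#' accuracy.
#'
#' @param trials data frame of all trials with columns `participant`, `task`,
#'   `pitch_level`, `duration_level`, `response`.
#' @param tasks tasks required for compliance.
#' @param sd_threshold passed to [outlier_flag()].
#' @return Data frame with one row per participant x task, including
#'   `included` (compliance), `outlier_pitch`, `outlier_duration`, and
#'   `accuracy_unambiguous`.
#' @export
cue_weights <- function(trials, tasks = c("emphasis", "stress", "boundary"),
                        sd_threshold = 3) {
  blocks <- split(trials, interaction(trials$participant, trials$task,
                                      drop = TRUE))
  res <- do.call(rbind, lapply(blocks, function(b) {
    cbind(data.frame(participant = b$participant[1], task = b$task[1]),
          firth_fit(b),
          data.frame(accuracy_unambiguous = unambiguous_accuracy(b)))
  }))
  rownames(res) <- NULL
  inc <- vapply(split(res, res$participant), compliance_filter, logical(1),
                tasks = tasks)
  res$included <- inc[as.character(res$participant)]
  res$outlier_pitch <- FALSE
  res$outlier_duration <- FALSE
  for (tk in unique(res$task)) {
    sel <- res$task == tk & res$included
    if (sum(sel) >= 3L) {
      res$outlier_pitch[sel] <- vapply(which(sel), function(i) {
        outlier_flag(res$beta_pitch[i], res$p_pitch[i],
                     res$beta_pitch[sel], sd_threshold = sd_threshold)
      }, logical(1))
      res$outlier_duration[sel] <- vapply(which(sel), function(i) {
        outlier_flag(res$beta_duration[i], res$p_duration[i],
                     res$beta_duration[sel], sd_threshold = sd_threshold)
      }, logical(1))
    }
  }
  res
}
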