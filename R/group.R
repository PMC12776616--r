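#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df (the large-sample
#' approximation appropriate for cohort-sized n).  Pairs with missing values
#' are dropped listwise.
#'
#' @param x,y numeric vectors of equal length (n >= 5 after NA removal).
#' @param exact if `TRUE` and n < 10, compute the p-value by exhaustive
#'   permutation of one vector instead of the t-approximation.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in ranks; Spearman correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (exact && n < 10L) {
    perms <- perm_matrix(n)
    null_rho <- apply(perms, 1L, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: with p sorted ascending,
#' `q_i = min_{j >= i} (m * p_j / j)`, clipped at 1, returned in the
#' original order (the standard BH procedure, via [stats::p.adjust()]).
#'
#' @param p vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value.
#'
#' @param r1,r2 the two correlations, strictly inside (-1, 1).
#' @param n1,n2 their sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| = 1: Fisher transform diverges", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Rank-standardize columns: z-scored average ranks, so that crossprod
# gives Spearman correlations.
rank_z <- function(M) {
  R <- apply(M, 2L, rank)
  R <- scale(R)
  R
}

#' Lag-resolved brain-behavior correlation
#'
#' Correlates the TRF weight at each retained lag (edge lags outside
#' `window_ms` are excluded) with the behavioral cue weight across
#' participants, using Spearman correlations with t-approximation p-values.
#'
#' @param weights participants x lags matrix of (channel-averaged) TRF
#'   weights.
#' @param behavior per-participant behavioral cue weight.
#' @param lag_ms lag grid in ms, one entry per weights column.
#' @param window_ms analysis window; lags outside it are dropped.
#' @return Data frame: `lag_ms`, `rho`, `p` for each retained lag.
#' @export
lagwise_correlation <- function(weights, behavior, lag_ms,
                                window_ms = c(0, 300)) {
  stopifnot(ncol(weights) == length(lag_ms),
            nrow(weights) == length(behavior))
  keep <- lag_ms >= window_ms[1] & lag_ms <= window_ms[2]
  W <- weights[, keep, drop = FALSE]
  res <- lapply(seq_len(ncol(W)), function(j) spearman(W[, j], behavior))
  data.frame(lag_ms = lag_ms[keep],
             rho = vapply(res, `[[`, numeric(1), "rho"),
             p = vapply(res, `[[`, numeric(1), "p"))
}

# Maximal runs of contiguous supra-threshold lags with a common rho sign.
# tstat supplies the per-lag cluster statistic; returns a data frame.
find_clusters <- function(lag_ms, rho, p, tstat, threshold) {
  supra <- p < threshold & rho != 0
  sgn <- sign(rho)
  out <- list()
  i <- 1L
  n <- length(supra)
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        start_ms = lag_ms[i], end_ms = lag_ms[j],
        mass = sum(tstat[i:j]), n_lags = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      mass = numeric(0), n_lags = integer(0)))
  }
  do.call(rbind, out)
}

rho_to_t <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  rho * sqrt((n - 2) / (1 - rho^2))
}

#' Cluster-based permutation correction for lag-resolved correlations
#'
#' Forms clusters as maximal runs of contiguous lags with p below
#' `cluster_threshold` and a common correlation sign, scored by the sum of
#' the per-lag t-statistics of rho.  The null distribution is the maximum
#' absolute cluster mass over lags from `n_perm` random permutations of the
#' behavior vector across participants (a fresh Spearman correlation per lag
#' per permutation).  Cluster p-values use the add-one rule
#' `(count + 1) / (n_perm + 1)`, so the observed labeling can never yield
#' p = 0.
#'
#' @inheritParams lagwise_correlation
#' @param n_perm number of permutations (a warning is logged below 100).
#' @param cluster_threshold per-lag inclusion threshold.
#' @param alpha significance level for clusters.
#' @param seed RNG seed for the permutations.
#' @return List: `lagwise` (data frame from [lagwise_correlation()]),
#'   `clusters` (data frame with `start_ms`, `end_ms`, `mass`, `p_cluster`,
#'   `significant`), `null_max_mass` (the permutation null sample).
#' @export
cluster_permutation <- function(weights, behavior, lag_ms,
                                window_ms = c(0, 300), n_perm = 1000L,
                                cluster_threshold = 0.05, alpha = 0.05,
                                seed = 1L) {
  if (n_perm < 100L) {
    warning("n_perm < 100 gives a coarse null distribution", call. = FALSE)
  }
  keep <- lag_ms >= window_ms[1] & lag_ms <= window_ms[2]
  W <- weights[, keep, drop = FALSE]
  lags_kept <- lag_ms[keep]
  n <- nrow(W)
  obs <- lagwise_correlation(weights, behavior, lag_ms, window_ms)
  obs_clusters <- find_clusters(obs$lag_ms, obs$rho, obs$p,
                                rho_to_t(obs$rho, n), cluster_threshold)

  # permutation null: Spearman = Pearson on (permuted) ranks, so shuffle the
  # behavior ranks and correlate against the fixed rank-standardized weights
  Wz <- rank_z(W)
  bz <- drop(rank_z(matrix(behavior, ncol = 1L)))
  set.seed(seed)
  t_crit <- stats::qt(1 - cluster_threshold / 2, df = n - 2)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rho_b <- drop(crossprod(Wz, bz[sample.int(n)])) / (n - 1)
    t_b <- rho_to_t(rho_b, n)
    cl <- find_clusters(lags_kept, rho_b,
                        ifelse(abs(t_b) > t_crit, 0, 1), t_b,
                        cluster_threshold)
    null_max[b] <- if (nrow(cl)) max(abs(cl$mass)) else 0
  }
  if (nrow(obs_clusters)) {
    obs_clusters$p_cluster <- vapply(obs_clusters$mass, function(m) {
      (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
    }, numeric(1))
    obs_clusters$significant <- obs_clusters$p_cluster < alpha
  } else {
    obs_clusters$p_cluster <- numeric(0)
    obs_clusters$significant <- logical(0)
  }
  list(lagwise = obs, clusters = obs_clusters, null_max_mass = null_max)
}

#' Tercile split and per-group summaries
#'
#' Ranks the cohort by a grouping variable and partitions it into three
#' near-equal groups (any remainder is distributed starting from the bottom
#' group, so group sizes differ by at most 1); ties are broken by stable
#' participant order.  Summarizes a per-participant quantity (vector, or a
#' matrix such as responses by morph level or TRF weights by lag) as group
#' means with standard errors.
#'
#' @param values numeric vector or participants x k matrix to summarize.
#' @param grouping per-participant grouping variable (e.g. behavioral pitch
#'   weight or neural tracking r); must not be constant.
#' @return List of class `tercile_summary`: `group` (factor low/mid/high per
#'   participant), `mean` and `sem` (3 x k matrices), `n` per group.
#' @export
tercile_summarize <- function(values, grouping) {
  n <- length(grouping)
  if (n < 6L) stop("need at least 6 participants", call. = FALSE)
  if (stats::sd(grouping) == 0) {
    stop("grouping variable is constant; terciles undefined", call. = FALSE)
  }
  V <- as.matrix(values)
  stopifnot(nrow(V) == n)
  base <- n %/% 3L
  extra <- n %% 3L
  sizes <- base + (seq_len(3L) <= extra)  # remainder from the bottom upward
  ord <- order(grouping)  # ties: stable participant order
  grp <- integer(n)
  grp[ord] <- rep(1:3, times = sizes)
  grp <- factor(grp, levels = 1:3, labels = c("low", "mid", "high"))
  m <- matrix(vapply(levels(grp),
                     function(g) colMeans(V[grp == g, , drop = FALSE]),
                     numeric(ncol(V))),
              nrow = 3L, ncol = ncol(V), byrow = TRUE,
              dimnames = list(levels(grp), colnames(V)))
  s <- matrix(vapply(levels(grp), function(g) {
    apply(V[grp == g, , drop = FALSE], 2L, stats::sd) / sqrt(sum(grp == g))
  }, numeric(ncol(V))),
  nrow = 3L, ncol = ncol(V), byrow = TRUE,
  dimnames = list(levels(grp), colnames(V)))
  structure(list(group = grp, mean = m, sem = s, n = sizes),
            class = "tercile_summary")
}
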