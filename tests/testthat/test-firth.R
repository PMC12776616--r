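test_that("symmetric response pattern yields exactly zero cue weights", {
  # responses invariant under level reversal + response complement: the
  # penalized likelihood is symmetric, so both slopes sit at 0
  grid <- expand.grid(pitch_level = 1:4, duration_level = 1:4)
  tab <- rbind(transform(grid, response = 0), transform(grid, response = 1))
  fit <- firth_fit(tab)
  expect_equal(fit$beta_pitch, 0, tolerance = 1e-6)
  expect_equal(fit$beta_duration, 0, tolerance = 1e-6)
  expect_equal(fit$beta_intercept, 0, tolerance = 1e-6)
})

test_that("estimates stay finite under complete separation and match the grid oracle", {
  # y = 1 iff pitch_level >= 3: plain ML diverges, the Jeffreys penalty
  # keeps the optimum finite
  grid <- expand.grid(pitch_level = 1:4, duration_level = 1:4)
  y <- as.integer(grid$pitch_level >= 3)
  fit <- firth_logistic(cbind(1, grid$pitch_level), y)
  expect_true(all(is.finite(fit$beta)))
  oracle <- firth_grid_oracle(grid$pitch_level, y)
  expect_equal(fit$beta[1], unname(oracle["b0"]), tolerance = 1e-4)
  expect_equal(fit$beta[2], unname(oracle["b1"]), tolerance = 1e-4)
})

test_that("the Jeffreys penalty equals the direct log-determinant", {
  set.seed(31)
  X <- cbind(1, rnorm(12), rbinom(12, 1, 0.5))
  y <- rbinom(12, 1, 0.5)
  beta <- c(0.3, -0.2, 0.5)
  pi <- plogis(drop(X %*% beta))
  direct <- 0.5 * log(det(t(X) %*% diag(pi * (1 - pi)) %*% X))
  # recompute through the same quantities the fitter uses
  W <- pi * (1 - pi)
  via_crossprod <- 0.5 * as.numeric(determinant(crossprod(X * W, X))$modulus)
  expect_equal(via_crossprod, direct, tolerance = 1e-10)
})

test_that("fit is invariant to row order and symmetric in the two cues", {
  tab <- make_trial_table(bp = 1.2, bd = 0.4, seed = 41)
  f1 <- firth_fit(tab)
  f2 <- firth_fit(tab[sample(nrow(tab)), ])
  expect_equal(f1$beta_pitch, f2$beta_pitch, tolerance = 1e-8)
  expect_equal(f1$p_pitch, f2$p_pitch, tolerance = 1e-8)

  swapped <- data.frame(pitch_level = tab$duration_level,
                        duration_level = tab$pitch_level,
                        response = tab$response)
  f3 <- firth_fit(swapped)
  expect_equal(f3$beta_pitch, f1$beta_duration, tolerance = 1e-10)
  expect_equal(f3$beta_duration, f1$beta_pitch, tolerance = 1e-10)
  expect_equal(f3$p_pitch, f1$p_duration, tolerance = 1e-10)
})

test_that("penalized likelihood at the optimum is at least its value at zero", {
  for (s in 1:5) {
    tab <- make_trial_table(bp = runif(1, -1, 2), bd = runif(1, -1, 2),
                            seed = 50 + s, n_reps = 4)
    X <- cbind(1, tab$pitch_level, tab$duration_level)
    fit <- firth_logistic(X, tab$response)
    pll0 <- {
      pi <- rep(0.5, nrow(X))
      I <- crossprod(X * 0.25, X)
      sum(log(0.5)) * nrow(X) + 0.5 * as.numeric(determinant(I)$modulus)
    }
    expect_gte(fit$pll, pll0 - 1e-10)
  }
})

test_that("penalized estimates approach the truth as trials accumulate", {
  errs <- sapply(1:30, function(s) {
    e160 <- abs(firth_fit(make_trial_table(1, 0.3, seed = s,
                                           n_reps = 10))$beta_pitch - 1)
    e800 <- abs(firth_fit(make_trial_table(1, 0.3, seed = 1000 + s,
                                           n_reps = 50))$beta_pitch - 1)
    c(e160, e800)
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("degenerate tables raise labeled errors", {
  expect_error(firth_fit(data.frame()), "empty")
  expect_error(firth_fit(data.frame(pitch_level = 5, duration_level = 1,
                                    response = 1)), "1-4")
})

test_that("compliance filter requires a significant cue on every task", {
  mk <- function(task, pp, pd) {
    data.frame(task = task, p_pitch = pp, p_duration = pd)
  }
  ok <- rbind(mk("emphasis", 0.01, 0.2), mk("stress", 0.2, 0.01),
              mk("boundary", 0.03, 0.6))
  expect_true(compliance_filter(ok))
  bad <- rbind(mk("emphasis", 0.01, 0.2), mk("stress", 0.3, 0.4),
               mk("boundary", 0.03, 0.6))
  expect_false(compliance_filter(bad))
  expect_error(compliance_filter(ok[1:2, ]), "boundary")
})

test_that("outlier flag needs both significance and cohort extremity", {
  cohort <- c(rnorm(20, 2, 1))
  expect_true(outlier_flag(-5, 0.001, c(cohort, -5)))
  expect_false(outlier_flag(-0.1, 0.4, c(cohort, -0.1)))
  expect_false(outlier_flag(5.5, 0.001, c(cohort, 5.5)))  # positive: never
  # constructed cohort: exactly the planted point is flagged
  set.seed(61)
  w <- rnorm(30, 1.5, 0.5)
  w[7] <- 1.5 - 4 * 0.5 * 3  # far below the mean
  p <- rep(0.01, 30)
  flags <- vapply(seq_along(w), function(i) outlier_flag(w[i], p[i], w),
                  logical(1))
  expect_equal(which(flags), 7L)
})

test_that("unambiguous accuracy scores only the agreeing corner cells", {
  tab <- make_trial_table(bp = 10, bd = 0, seed = 71)  # follows pitch only
  expect_equal(unambiguous_accuracy(tab), 1.0)
  # all-consistent responder
  tab2 <- expand.grid(pitch_level = c(1, 4), duration_level = c(1, 4))
  tab2 <- tab2[rep(1:4, 5), ]
  tab2$response <- as.integer(tab2$pitch_level == 4)
  tab2$response[tab2$pitch_level != tab2$duration_level] <- NA
  tab2$response[is.na(tab2$response)] <- 0
  expect_equal(unambiguous_accuracy(tab2[tab2$pitch_level == tab2$duration_level, ]),
               1.0)
  expect_error(unambiguous_accuracy(
    data.frame(pitch_level = 2, duration_level = 2, response = 1)),
    "unambiguous")
})

test_that("cohort-level cue weights carry inclusion and outlier flags", {
  tabs <- do.call(rbind, lapply(1:6, function(i) {
    do.call(rbind, lapply(c("emphasis", "stress", "boundary"), function(tk) {
      tb <- make_trial_table(bp = 1, bd = 0.5, seed = i * 10 +
                               match(tk, c("emphasis", "stress", "boundary")),
                             participant = paste0("P", i), task = tk)
      tb
    }))
  }))
  cw <- cue_weights(tabs)
  expect_equal(nrow(cw), 18)
  expect_true(all(c("included", "outlier_pitch", "accuracy_unambiguous")
                  %in% names(cw)))
  expect_true(all(cw$p_pitch > 0 & cw$p_pitch <= 1))
  expect_true(all(cw$included))  # strong true slopes: everyone complies
})
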