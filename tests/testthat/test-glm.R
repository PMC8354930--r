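test_that("the canonical HRF peaks near 5 s with unit amplitude and zero onset", {
  # independent oracle: evaluate the difference-of-gammas density on a fine
  # grid and locate its maximum
  tg <- seq(0, 32, by = 0.001)
  dg <- dgamma(tg, 6, 1) - dgamma(tg, 16, 1) / 6
  peak_oracle <- tg[which.max(dg)]
  for (dt in c(0.1, 0.5, 2)) {
    h <- canonical_hrf(dt)
    expect_equal(h[1], 0)
    expect_equal(max(h), 1)
    expect_lt(abs((which.max(h) - 1) * dt - peak_oracle), dt + 1e-9)
  }
  expect_error(canonical_hrf(0), "dt")
  expect_error(canonical_hrf(-1), "dt")
})

test_that("the full beta-series design has 384 interest regressors, one run has 48", {
  full <- build_design_matrix(quick_schedules(1))
  expect_equal(full$interest_count, 384)
  expect_equal(nrow(full$matrix), 8 * 210)
  one <- build_design_matrix(quick_schedules(1)[1])
  expect_equal(one$interest_count, 48)
  # nuisance block: per-run intercept and a 128-s discrete-cosine basis
  expect_true(all(c("intercept", "dct1", "dct6") %in% one$labels$tag))
})

test_that("zero-duration events are rejected", {
  sch <- build_run_schedule(0, 1)
  sch$trials$execution_duration <- 0
  expect_error(build_design_matrix(list(sch)), "positive")
})

test_that("OLS coefficients match an independent pseudoinverse oracle", {
  design <- build_design_matrix(quick_schedules(2)[1:2])
  set.seed(42)
  Y <- matrix(rnorm(nrow(design$matrix) * 7), ncol = 7)
  fit <- fit_glm_ols(Y, design)
  pinv_beta <- MASS::ginv(design$matrix) %*% Y
  expect_lt(max(abs(fit$coefficients - pinv_beta)), 1e-8)
})

test_that("noiseless simulated data invert to the injected patterns exactly", {
  schedules <- quick_schedules(4)[1:3]
  pats <- quick_patterns(n_voxels = 12, seed = 9)
  silent <- noise_spec(sigma = 0, ar1_rho = 0, drift_amplitude = 0)
  runs <- lapply(schedules, function(s) {
    simulate_roi_run(s, pats, silent, seed = 1)
  })
  design <- build_design_matrix(schedules)
  fit <- fit_glm_ols(runs, design)
  for (ph in c("planning", "execution")) {
    bp <- extract_phase_patterns(fit, ph)
    expect_equal(nrow(bp$patterns), 48)
    for (i in seq_len(nrow(bp$patterns))) {
      truth <- pats[[ph]][[bp$labels$condition[i]]]
      expect_lt(max(abs(bp$patterns[i, ] - truth)), 1e-8)
    }
  }
})

test_that("nuisance columns orthogonal to the interest block leave betas unchanged", {
  schedules <- quick_schedules(6)[1:2]
  design0 <- build_design_matrix(schedules)
  set.seed(7)
  raw <- lapply(schedules, function(s) {
    matrix(rnorm(run_volume_count(s) * 6), ncol = 6)
  })
  # orthogonalise the motion columns against the existing design
  X <- design0$matrix
  proj <- X %*% solve(crossprod(X), crossprod(X, do.call(rbind, raw)))
  ortho <- do.call(rbind, raw) - proj
  rows <- c(0, cumsum(vapply(schedules, run_volume_count, integer(1))))
  motion <- lapply(seq_along(schedules), function(r) {
    ortho[(rows[r] + 1):rows[r + 1], , drop = FALSE]
  })
  design1 <- build_design_matrix(schedules, motion = motion)
  Y <- matrix(rnorm(nrow(X) * 5), ncol = 5)
  b0 <- fit_glm_ols(Y, design0)
  b1 <- fit_glm_ols(Y, design1)
  sel0 <- b0$labels$type == "interest"
  sel1 <- b1$labels$type == "interest"
  expect_lt(max(abs(b0$coefficients[sel0, ] - b1$coefficients[sel1, ])), 1e-8)
})

test_that("rank-deficient designs fail loudly naming the collinear columns", {
  schedules <- quick_schedules(1)[1]
  design <- build_design_matrix(schedules)
  design$matrix <- cbind(design$matrix, design$matrix[, 1])
  design$labels <- rbind(design$labels, design$labels[1, ])
  Y <- matrix(rnorm(210 * 2), ncol = 2)
  expect_error(fit_glm_ols(Y, design), "rank deficient")
})

test_that("error trials are absorbed into a nuisance regressor and dropped from patterns", {
  schedules <- quick_schedules(8)[1:2]
  design <- build_design_matrix(schedules,
                                error_trials = list(c(0L, 5L), integer(0)))
  expect_equal(design$interest_count, 2 * 48 - 6)
  expect_true("error" %in% design$labels$tag)
  Y <- matrix(rnorm(420 * 3), ncol = 3)
  bp <- extract_phase_patterns(fit_glm_ols(Y, design), "planning")
  expect_equal(nrow(bp$patterns), 30)
  expect_true(all(bp$labels$phase == "planning"))
})
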