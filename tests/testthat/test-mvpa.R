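test_that("leave-one-run-out folds test each run exactly once", {
  folds <- make_loro_folds(8)
  expect_length(folds, 8)
  expect_setequal(vapply(folds, function(f) f$test, numeric(1)), 0:7)
  for (f in folds) {
    expect_length(f$train, 7)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_length(make_loro_folds(c(0, 1)), 2)
  expect_error(make_loro_folds(1), "at least 2")
})

test_that("trial balancing equalises per-run condition counts and is seeded", {
  schedules <- quick_schedules(12)[1:4]
  design <- build_design_matrix(schedules,
                                error_trials = list(integer(0), 3L,
                                                    integer(0), integer(0)))
  Y <- matrix(rnorm(4 * 210 * 6), ncol = 6)
  bp <- extract_phase_patterns(fit_glm_ols(Y, design), "planning")
  bal <- balance_trials(bp, seed = 4)
  counts <- table(bal$labels$run, bal$labels$condition)
  expect_true(all(counts[2, ] == 3))
  expect_true(all(counts[-2, ] == 4))
  # already-balanced input passes through untouched
  bp0 <- extract_phase_patterns(
    fit_glm_ols(Y, build_design_matrix(schedules)), "planning")
  expect_identical(balance_trials(bp0, seed = 1)$patterns, bp0$patterns)
  # determinism
  expect_identical(balance_trials(bp, seed = 4)$labels,
                   balance_trials(bp, seed = 4)$labels)
})

test_that("the shrinkage LDA discriminant matches the closed-form toy case", {
  train_x <- rbind(c(-1, 1), c(-1, -1), c(-1, 0), c(1, 1), c(1, -1), c(1, 0))
  train_y <- rep(c("a", "b"), each = 3)
  # full shrinkage to the scaled identity: w is along mu1 - mu0 = (2, 0)
  pred <- lda_fit_predict(train_x, train_y, rbind(c(0.5, 7)), shrinkage = 1)
  expect_equal(pred, "b")
  pred0 <- lda_fit_predict(train_x, train_y, rbind(c(-0.5, -7)), shrinkage = 1)
  expect_equal(pred0, "a")
  # exact tie goes to the first class level
  expect_equal(lda_fit_predict(train_x, train_y, rbind(c(0, 3)), shrinkage = 1),
               "a")
})

test_that("LDA predictions agree with an explicit dense-inverse oracle", {
  set.seed(31)
  for (rep in 1:20) {
    p <- sample(3:8, 1)
    n <- sample(c(20, 40), 1)
    mu <- rnorm(p)
    train_x <- rbind(matrix(rnorm(n * p), n) ,
                     matrix(rnorm(n * p, mean = rep(mu, each = n)), n))
    train_y <- rep(c("m", "u"), each = n)
    test_x <- matrix(rnorm(15 * p), 15)
    lambda <- runif(1, 0.1, 0.9)
    expect_identical(
      lda_fit_predict(train_x, train_y, test_x, shrinkage = lambda),
      as.vector(lda_oracle(train_x, train_y, test_x, lambda))
    )
  }
})

test_that("separable classes are classified perfectly despite a degenerate direction", {
  set.seed(8)
  n <- 12
  base <- matrix(rnorm(2 * n * 4), 2 * n, 4)
  base[, 2] <- 0                      # zero-variance direction
  base[1:n, 1] <- base[1:n, 1] - 10
  base[(n + 1):(2 * n), 1] <- base[(n + 1):(2 * n), 1] + 10
  y <- rep(c("a", "b"), each = n)
  pred <- lda_fit_predict(base, y, base, shrinkage = "lw")
  expect_equal(mean(pred == y), 1)
})

test_that("label-permuted training yields chance-level accuracy", {
  set.seed(99)
  accs <- replicate(200, {
    train_x <- matrix(rnorm(60 * 4), 60)
    train_y <- sample(rep(c("m", "u"), each = 30))
    test_x <- matrix(rnorm(40 * 4), 40)
    test_y <- rep(c("m", "u"), each = 20)
    mean(lda_fit_predict(train_x, train_y, test_x, "lw") == test_y)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("action and goal decoding report fold-mean accuracies with the stated geometry", {
  sub <- simulate_subject(1, 321, n_voxels = 40, rois = "aIPS", n_runs = 4)
  design <- build_design_matrix(sub$schedules)
  Y <- do.call(rbind, lapply(sub$data$aIPS, function(ts) t(ts$data)))
  bp <- extract_phase_patterns(fit_glm_ols(Y, design), "execution",
                               roi_name = "aIPS", subject_id = sub$subject_id)
  folds <- make_loro_folds(unique(bp$labels$run))
  act <- decode_within_tool_action(bp, folds)
  goal <- decode_cross_tool_goal(bp, folds)
  expect_equal(act$comparison, "action")
  expect_equal(goal$comparison, "goal")
  expect_equal(act$accuracy, mean(act$per_fold))
  expect_equal(goal$accuracy, mean(goal$per_fold))
  expect_length(act$per_fold, 4)
  expect_equal(act$n_train_per_class, 12)  # 4 trials x 3 training runs
  expect_equal(act$n_test_per_class, 4)
  # strong signal in this ROI/phase: both decoders clear chance comfortably
  expect_gt(act$accuracy, 0.6)
  expect_gt(goal$accuracy, 0.6)
})

test_that("accuracy is invariant to a common affine rescaling of the patterns", {
  sub <- simulate_subject(2, 55, n_voxels = 25, rois = "SPL", n_runs = 3)
  design <- build_design_matrix(sub$schedules)
  Y <- do.call(rbind, lapply(sub$data$SPL, function(ts) t(ts$data)))
  bp <- extract_phase_patterns(fit_glm_ols(Y, design), "planning",
                               roi_name = "SPL")
  folds <- make_loro_folds(unique(bp$labels$run))
  a1 <- decode_within_tool_action(bp, folds)$accuracy
  bp2 <- bp
  bp2$patterns <- bp$patterns * 3.7 + 1.2
  a2 <- decode_within_tool_action(bp2, folds)$accuracy
  expect_equal(a1, a2)
})

test_that("without a shared goal axis cross-decoding cannot beat within-tool decoding", {
  # goal code absent: the action code does not transfer across tools
  prof <- default_encoding_profile(1.2, 0)
  accs <- do.call(rbind, lapply(1:6, function(s) {
    decode_subject(simulate_subject(s, 500 + s, profile = prof,
                                    n_voxels = 40, rois = "PMd", n_runs = 4))
  }))
  within <- mean(accs$accuracy[accs$comparison == "action" &
                                 accs$phase == "execution"])
  cross <- mean(accs$accuracy[accs$comparison == "goal" &
                                accs$phase == "execution"])
  expect_gt(within, 0.75)
  expect_lt(abs(cross - 0.5), 0.12)
  expect_lt(cross, within)
})
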