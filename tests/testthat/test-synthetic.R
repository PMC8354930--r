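test_that("condition patterns combine a tool-specific action code and a shared goal code", {
  prof <- default_encoding_profile(1, 1, planning_scale = 1)
  pats <- make_condition_patterns(prof, "aIPS", "execution", 60, seed = 3)
  expect_length(pats, 4)
  # with the goal component removed, the four action vectors are orthogonal
  prof_a <- default_encoding_profile(1, 0)
  pa <- make_condition_patterns(prof_a, "aIPS", "execution", 60, seed = 3)
  expect_lt(abs(sum(pa$move_scissors * pa$move_axe)), 1e-10)
  expect_lt(abs(sum(pa$use_scissors * pa$move_axe)), 1e-10)
  # with the action component removed, tools are indistinguishable and the
  # two actions are opposite along the goal axis
  prof_g <- default_encoding_profile(0, 1)
  pg <- make_condition_patterns(prof_g, "aIPS", "execution", 60, seed = 3)
  expect_equal(pg$move_scissors, pg$move_axe)
  expect_equal(pg$use_scissors, -pg$move_scissors)
  expect_error(make_condition_patterns(prof, "aIPS", "execution", 1, 1),
               "n_voxels")
})

test_that("the default profile encodes the study's significance map", {
  prof <- default_encoding_profile()
  gains <- function(roi, ph) prof[prof$roi == roi & prof$phase == ph, ]
  # M1 carries nothing at planning: all four patterns identical (flat)
  p_m1 <- make_condition_patterns(prof, "M1", "planning", 20, seed = 1)
  expect_true(all(vapply(p_m1, function(p) all(p == p_m1[[1]]), logical(1))))
  expect_gt(gains("M1", "execution")$action_gain, 0)
  expect_equal(gains("M1", "execution")$goal_gain, 0)
  for (roi in c("pMTG", "aIPS", "SPL", "SPOC")) {
    expect_gt(gains(roi, "planning")$goal_gain, 0)
  }
  expect_equal(gains("SMG", "planning")$goal_gain, 0)
  expect_gt(gains("SMG", "execution")$goal_gain, 0)
  expect_gt(gains("PMv", "execution")$goal_gain, 0)
  expect_equal(gains("SPOC", "execution")$goal_gain, 0)
  # cue phase carries no condition information
  expect_true(all(prof[prof$phase == "cue", c("action_gain", "goal_gain")] == 0))
})

test_that("zero gains and zero noise give a flat time series", {
  pats <- quick_patterns(null_encoding_profile(), n_voxels = 5)
  ts <- simulate_roi_run(build_run_schedule(0, 1), pats,
                         noise_spec(0, 0, 0), seed = 1)
  expect_equal(dim(ts$data), c(5, 210))
  expect_true(all(ts$data == 0))
})

test_that("residual noise has the requested lag-1 autocorrelation", {
  e <- local({
    set.seed(2024)
    toolnet:::ar1_noise(1, 10000, sigma = 1, rho = 0.3)
  })
  r1 <- cor(e[1, -1], e[1, -10000])
  expect_lt(abs(r1 - 0.3), 0.05)
  expect_lt(abs(sd(e) - 1), 0.05)
})

test_that("noise specifications are validated", {
  expect_error(noise_spec(ar1_rho = 1), "ar1_rho")
  expect_error(noise_spec(sigma = -1), "sigma")
  expect_error(noise_spec(drift_amplitude = -0.1), "drift")
})

test_that("simulated subjects are reproducible from the master seed", {
  a <- simulate_subject(1, 77, n_voxels = 10, rois = c("pMTG", "M1"), n_runs = 2)
  b <- simulate_subject(1, 77, n_voxels = 10, rois = c("pMTG", "M1"), n_runs = 2)
  expect_identical(a$data$pMTG[[1]]$data, b$data$pMTG[[1]]$data)
  c <- simulate_subject(2, 77, n_voxels = 10, rois = c("pMTG", "M1"), n_runs = 2)
  expect_false(identical(a$data$pMTG[[1]]$data, c$data$pMTG[[1]]$data))
})

test_that("cross-decoding transfer grows with the shared goal gain", {
  # pattern-level check: the discriminant learned on one tool generalises to
  # the other in proportion to the goal gain
  transfer <- vapply(c(0, 0.5, 1, 2), function(gg) {
    prof <- default_encoding_profile(1, gg)
    pats <- make_condition_patterns(prof, "aIPS", "execution", 80, seed = 5)
    w <- pats$move_axe - pats$use_axe
    sum(w * (pats$move_scissors - pats$use_scissors))
  }, numeric(1))
  expect_equal(transfer[1], 0)
  expect_true(all(diff(transfer) > 0))
})
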