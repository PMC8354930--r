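test_that("the first eigenvariate summarises an ROI as specified", {
  set.seed(5)
  x <- rnorm(50)
  single <- first_eigenvariate(matrix(x, 1))
  expect_equal(single, as.numeric(scale(x)), ignore_attr = TRUE)
  # exact rank-1 data recover the timecourse up to scale and sign
  u <- runif(20); v <- rnorm(100)
  e <- first_eigenvariate(u %o% v)
  expect_gt(abs(cor(e, v)), 1 - 1e-10)
  expect_equal(sd(e), 1)
  expect_error(first_eigenvariate(matrix(1, 5, 30)), "constant")
})

test_that("the first eigenvariate matches an independent spectral oracle", {
  set.seed(12)
  data <- matrix(rnorm(50 * 210), 50) + outer(runif(50), sin(1:210 / 9))
  e <- first_eigenvariate(data)
  # oracle: leading eigenvector of the volumes x volumes covariance
  Xc <- sweep(t(data), 2, colMeans(t(data)))
  oracle <- eigen(tcrossprod(Xc), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(cor(e, oracle)), 0.999)
})

test_that("the shipped model space has 15 models and a fully modulated model 1", {
  space <- build_model_space()
  expect_length(space, 15)
  expect_equal(sum(space[[1]]$b_support), 6)
  expect_true(all(!diag(space[[1]]$b_support)))
  for (m in space) {
    expect_gt(sum(m$b_support), 0)
    expect_true(all(!diag(m$b_support)))
  }
  expect_equal(vapply(space, function(m) m$model_id, integer(1)), 1:15)
  # every model's support is unique
  keys <- vapply(space, function(m) paste(m$b_support + 0, collapse = ""),
                 character(1))
  expect_false(any(duplicated(keys)))
})

test_that("the resting state is a fixed point of the forward model", {
  truth <- default_dcm_truth()
  u0 <- list(u_task = numeric(2000), u_drive = numeric(2000),
             dt = 0.05, tr = 2, n_volumes = 50)
  bold <- integrate_bilinear_dcm(truth$A, truth$B, truth$C, u0)
  expect_lt(max(abs(bold)), 1e-12)
})

test_that("without coupling paths only the driven node responds", {
  A <- diag(-0.5, 3)
  B <- matrix(0, 3, 3)
  C <- c(1, 0, 0)
  u <- dcm_inputs_from_schedule(build_run_schedule(0, 1))
  out <- integrate_bilinear_dcm(A, B, C, u, return_neural = TRUE)
  expect_gt(max(abs(out$bold[, "pMTG"])), 1e-3)
  expect_lt(max(abs(out$bold[, c("aIPS", "PMv")])), 1e-12)
})

test_that("zero modulation makes the output independent of the task input", {
  truth <- default_dcm_truth()
  u <- dcm_inputs_from_schedule(build_run_schedule(0, 1))
  u_off <- u; u_off$u_task <- numeric(length(u$u_task))
  b0 <- matrix(0, 3, 3)
  expect_equal(integrate_bilinear_dcm(truth$A, b0, truth$C, u),
               integrate_bilinear_dcm(truth$A, b0, truth$C, u_off))
})

test_that("the neural subsystem is linear in the driving input when B = 0", {
  A <- default_dcm_truth()$A
  u <- dcm_inputs_from_schedule(build_run_schedule(0, 1))
  z1 <- integrate_bilinear_dcm(A, matrix(0, 3, 3), c(1, 0, 0), u,
                               return_neural = TRUE)$neural
  z2 <- integrate_bilinear_dcm(A, matrix(0, 3, 3), c(2, 0, 0), u,
                               return_neural = TRUE)$neural
  expect_lt(max(abs(z2 - 2 * z1)), 1e-6)
})

test_that("halving the integration step changes the BOLD output negligibly", {
  truth <- default_dcm_truth()
  sch <- build_run_schedule(0, 1)
  y1 <- integrate_bilinear_dcm(truth$A, truth$B, truth$C,
                               dcm_inputs_from_schedule(sch, dt = 0.05))
  y2 <- integrate_bilinear_dcm(truth$A, truth$B, truth$C,
                               dcm_inputs_from_schedule(sch, dt = 0.025))
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-4)
})

test_that("unstable intrinsic coupling is rejected naming the eigenvalue", {
  A <- matrix(0.6, 3, 3); diag(A) <- -0.1
  u <- dcm_inputs_from_schedule(build_run_schedule(0, 1))
  expect_error(integrate_bilinear_dcm(A, matrix(0, 3, 3), c(1, 0, 0), u),
               "unstable")
})

test_that("a model with no free parameters inverts to its prior", {
  fixed <- dcm_model(99L, matrix(FALSE, 3, 3))
  u <- dcm_inputs_from_schedule(build_run_schedule(0, 1))
  truth <- default_dcm_truth()
  y <- integrate_bilinear_dcm(truth$A, matrix(0, 3, 3), truth$C, u)
  fit <- invert_dcm(y, fixed, u, free_a = FALSE, free_self = FALSE,
                    free_c = FALSE)
  expect_length(fit$theta, 0)
  expect_equal(unname(diag(fit$A)), rep(-0.5, 3))
  expect_true(all(fit$B == 0) && all(fit$C == 0))
  # evidence equals the (concentrated) log-likelihood at the prior mean
  tmpl <- toolnet:::param_template(fixed, dcm_priors(), FALSE, FALSE, FALSE)
  nlj <- toolnet:::dcm_neg_log_joint(numeric(0), y, fixed, u, dcm_priors(),
                                     default_hemo_params(), tmpl)
  expect_equal(fit$log_evidence, -nlj)
})

test_that("random-effects BMS behaves correctly in symmetric and decisive cases", {
  lme <- matrix(0, 6, 2)
  bms <- rfx_bms(lme, n_samples = 2e5, seed = 2)
  expect_lt(abs(bms$exceedance[1] - 0.5), 0.01)
  expect_lt(abs(sum(bms$exceedance) - 1), 0.005)
  # 17 subjects all favouring model 1 by 10 log-units over 5 competitors
  lme2 <- matrix(0, 17, 6)
  lme2[, 1] <- 10
  bms2 <- rfx_bms(lme2, n_samples = 2e5, seed = 3)
  expect_gt(bms2$exceedance[1], 0.99)
  expect_true(all(bms2$alpha >= 1))
  expect_error(rfx_bms(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("group tests on connection parameters match the two-sided t-test", {
  set.seed(9)
  pos <- cbind(strong = rnorm(17, 0.3, 0.05), null = rnorm(17, 0, 0.1))
  res <- group_test_parameters(pos)
  expect_true(res$significant[res$parameter == "strong"])
  expect_false(res$significant[res$parameter == "null"])
  ref <- t.test(pos[, 1], mu = 0)
  expect_lt(abs(res$t[1] - unname(ref$statistic)), 1e-10)
  expect_lt(abs(res$p[1] - ref$p.value), 1e-10)
})

test_that("zero-mean parameters rarely reach significance under FDR", {
  set.seed(71)
  hits <- replicate(200, {
    pos <- matrix(rnorm(17 * 6, 0, 0.2), 17, 6,
                  dimnames = list(NULL, paste0("b", 1:6)))
    any(group_test_parameters(pos)$significant)
  })
  expect_lt(mean(hits), 0.05)
})
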