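# Shared fixtures: small simulated objects rebuilt at test time.

quick_schedules <- function(seed = 1, n_runs = 8) {
  build_session_schedules(seed, n_runs = n_runs)
}

# A small single-ROI subject-like dataset for GLM/decoding tests.
quick_patterns <- function(profile = default_encoding_profile(), roi = "aIPS",
                           n_voxels = 30, seed = 1) {
  out <- list()
  for (ph in phase_names()) {
    out[[ph]] <- make_condition_patterns(profile, roi, ph, n_voxels, seed)
  }
  out
}

# Brute-force Benjamini-Yekutieli step-up oracle: largest k with
# p_(k) <= k q / (m c(m)); reject the k smallest p-values.
by_stepup_oracle <- function(p, q = 0.05) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / (m * cm)) k <- i
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}

# Independent shrinkage-LDA oracle using an explicit dense matrix inverse.
lda_oracle <- function(train_x, train_y, test_x, lambda) {
  classes <- sort(unique(train_y))
  x0 <- train_x[train_y == classes[1], , drop = FALSE]
  x1 <- train_x[train_y == classes[2], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  xc <- rbind(sweep(x0, 2, mu0), sweep(x1, 2, mu1))
  S <- t(xc) %*% xc / nrow(xc)
  p <- ncol(train_x)
  S_sh <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(p)
  w <- solve(S_sh) %*% (mu1 - mu0)
  scores <- test_x %*% w
  thr <- sum(w * (mu0 + mu1)) / 2
  ifelse(scores > thr, classes[2], classes[1])
}
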