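# ROI decoding: shrinkage LDA under leave-one-run-out cross-validation.
# Action decoding trains and tests move-vs-use within a tool and averages
# the two tools; goal cross-decoding trains on one tool and tests on the
# other (both directions averaged), so only a tool-invariant code transfers.

#' Leave-one-run-out cross-validation folds
#'
#' @param runs Vector of run identifiers (>= 2 distinct runs), or a single
#'   integer `n` meaning runs `0:(n-1)`.
#' @return A `fold_plan`: list of folds, each a list with `train` (run ids)
#'   and `test` (one run id); every run is the test run exactly once.
#' @export
make_loro_folds <- function(runs) {
  if (length(runs) == 1) {
    if (runs < 2) stop("leave-one-run-out needs at least 2 runs")
    runs <- seq_len(runs) - 1L
  }
  runs <- sort(unique(runs))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  structure(lapply(runs, function(r) list(train = setdiff(runs, r), test = r)),
            class = "fold_plan")
}

#' Balance trial counts across conditions within each run
#'
#' Error-trial exclusion can leave unequal condition counts; within each run
#' every condition is randomly subsampled to that run's minimum
#' per-condition count, so the classifier always sees equally many trials
#' per condition. Runs that are already balanced are returned untouched
#' (no randomness consumed).
#'
#' @param bp A `beta_patterns`.
#' @param seed Integer seed for the subsampling.
#' @return A `beta_patterns` with balanced per-run condition counts, row
#'   order preserved.
#' @export
balance_trials <- function(bp, seed = 1) {
  stopifnot(inherits(bp, "beta_patterns"))
  lab <- bp$labels
  keep <- rep(TRUE, nrow(lab))
  conds <- enumerate_conditions()$condition
  for (r in sort(unique(lab$run))) {
    counts <- vapply(conds, function(cd) sum(lab$run == r & lab$condition == cd),
                     integer(1))
    if (any(counts == 0)) {
      stop("run ", r, " has no trials for condition ",
           paste(conds[counts == 0], collapse = ", "))
    }
    m <- min(counts)
    for (cd in conds[counts > m]) {
      idx <- which(lab$run == r & lab$condition == cd)
      drop_n <- length(idx) - m
      drop <- local_seed(derive_seed(seed, 23L, r, match(cd, conds)),
                         sample(idx, drop_n))
      keep[drop] <- FALSE
    }
  }
  bp$patterns <- bp$patterns[keep, , drop = FALSE]
  bp$labels <- bp$labels[keep, , drop = FALSE]
  bp
}

# Ledoit-Wolf analytic shrinkage intensity toward the scaled identity,
# computed from within-class-centered rows.
ledoit_wolf_lambda <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  if (d2 < .Machine$double.eps) return(1)
  b2bar <- (sum(rowSums(Xc^2)^2) / n^2 - sum(S^2) / n) / p
  b2 <- min(b2bar, d2)
  b2 / d2
}

#' Shrinkage linear discriminant analysis: fit and predict
#'
#' Fits class means and the pooled within-class covariance shrunk toward its
#' average-variance diagonal, `S(lambda) = (1 - lambda) S + lambda m I` with
#' `m = tr(S)/p`, then classifies by the linear discriminant
#' `w = S(lambda)^{-1} (mu_1 - mu_0)` with the midpoint threshold. The
#' default `shrinkage = "lw"` uses the Ledoit-Wolf analytic intensity; a
#' numeric value in `[0, 1]` fixes it. Exact ties on the boundary go to the
#' first class level. Deterministic.
#'
#' @param train_x,train_y Training patterns (rows) and two-class labels.
#' @param test_x Test patterns.
#' @param shrinkage `"lw"` or a fraction in `[0, 1]`.
#' @return Character vector of predicted labels for the rows of `test_x`.
#' @export
lda_fit_predict <- function(train_x, train_y, test_x, shrinkage = "lw") {
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  if (length(classes) != 2) stop("exactly two classes are required")
  if (min(table(train_y)) < 2) stop("at least 2 training rows per class")
  train_x <- as.matrix(train_x)
  test_x <- matrix(as.matrix(test_x), ncol = ncol(train_x))
  mu0 <- colMeans(train_x[train_y == classes[1], , drop = FALSE])
  mu1 <- colMeans(train_x[train_y == classes[2], , drop = FALSE])
  Xc <- train_x
  Xc[train_y == classes[1], ] <- sweep(train_x[train_y == classes[1], ,
                                               drop = FALSE], 2, mu0)
  Xc[train_y == classes[2], ] <- sweep(train_x[train_y == classes[2], ,
                                               drop = FALSE], 2, mu1)
  p <- ncol(train_x)
  S <- crossprod(Xc) / nrow(Xc)
  lambda <- if (identical(shrinkage, "lw")) ledoit_wolf_lambda(Xc)
            else {
              if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
                stop("`shrinkage` must be \"lw\" or a fraction in [0, 1]")
              shrinkage
            }
  m <- sum(diag(S)) / p
  S_sh <- (1 - lambda) * S + diag(lambda * m, p)
  w <- tryCatch(solve(S_sh, mu1 - mu0), error = function(e) {
    stop("shrunk covariance is singular (lambda = ", signif(lambda, 3),
         "); increase the shrinkage intensity")
  })
  thresh <- sum(w * (mu0 + mu1)) / 2
  scores <- drop(test_x %*% w)
  ifelse(scores > thresh, classes[2], classes[1])
}

new_decoding_result <- function(bp, phase, comparison, per_fold,
                                n_train, n_test) {
  structure(
    list(subject_id = bp$subject_id, roi_name = bp$roi_name, phase = phase,
         comparison = comparison, accuracy = mean(per_fold),
         per_fold = per_fold, n_train_per_class = n_train,
         n_test_per_class = n_test),
    class = "decoding_result"
  )
}

#' Within-tool action decoding (move vs use)
#'
#' For each tool separately, the classifier is trained to discriminate
#' grasp-to-move from grasp-to-use on the training runs of each fold and
#' tested on the held-out run; the reported accuracy is the mean of the two
#' tools' leave-one-run-out accuracies.
#'
#' @param bp A balanced `beta_patterns` for one phase.
#' @param folds A `fold_plan` (default: leave-one-run-out over the runs
#'   present).
#' @param shrinkage Passed to [lda_fit_predict()].
#' @return A `decoding_result` with `comparison = "action"`.
#' @export
decode_within_tool_action <- function(bp, folds = NULL, shrinkage = "lw") {
  stopifnot(inherits(bp, "beta_patterns"))
  lab <- bp$labels
  if (is.null(folds)) folds <- make_loro_folds(unique(lab$run))
  phase <- unique(lab$phase)
  stopifnot(length(phase) == 1)
  tools <- c("scissors", "axe")
  per_fold <- numeric(length(folds))
  n_train <- n_test <- integer(0)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    accs <- vapply(tools, function(tl) {
      tr <- lab$tool == tl & lab$run %in% fold$train
      te <- lab$tool == tl & lab$run %in% fold$test
      pred <- lda_fit_predict(bp$patterns[tr, , drop = FALSE], lab$action[tr],
                              bp$patterns[te, , drop = FALSE], shrinkage)
      n_train <<- c(n_train, sum(tr) / 2); n_test <<- c(n_test, sum(te) / 2)
      mean(pred == lab$action[te])
    }, numeric(1))
    per_fold[fi] <- mean(accs)
  }
  new_decoding_result(bp, phase, "action", per_fold,
                      round(mean(n_train)), round(mean(n_test)))
}

#' Cross-tool goal decoding (move vs use, generalised across tools)
#'
#' Direction one trains move-vs-use on the axe trials of each fold's
#' training runs and tests on the scissors trials of the held-out run;
#' direction two swaps the tools. The reported accuracy is the mean over
#' both directions and all folds. Above-chance accuracy requires a goal
#' code shared across tools.
#'
#' @inheritParams decode_within_tool_action
#' @return A `decoding_result` with `comparison = "goal"`.
#' @export
decode_cross_tool_goal <- function(bp, folds = NULL, shrinkage = "lw") {
  stopifnot(inherits(bp, "beta_patterns"))
  lab <- bp$labels
  if (is.null(folds)) folds <- make_loro_folds(unique(lab$run))
  phase <- unique(lab$phase)
  stopifnot(length(phase) == 1)
  directions <- list(c(train = "axe", test = "scissors"),
                     c(train = "scissors", test = "axe"))
  per_fold <- numeric(length(folds))
  n_train <- n_test <- integer(0)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    accs <- vapply(directions, function(dir) {
      tr <- lab$tool == dir[["train"]] & lab$run %in% fold$train
      te <- lab$tool == dir[["test"]] & lab$run %in% fold$test
      pred <- lda_fit_predict(bp$patterns[tr, , drop = FALSE], lab$action[tr],
                              bp$patterns[te, , drop = FALSE], shrinkage)
      n_train <<- c(n_train, sum(tr) / 2); n_test <<- c(n_test, sum(te) / 2)
      mean(pred == lab$action[te])
    }, numeric(1))
    per_fold[fi] <- mean(accs)
  }
  new_decoding_result(bp, phase, "goal", per_fold,
                      round(mean(n_train)), round(mean(n_test)))
}

#' Decode one simulated (or ingested) subject across ROIs and phases
#'
#' Fits the trial-wise GLM once per ROI on the concatenated runs, extracts
#' planning- and execution-phase beta patterns, balances trials, and runs
#' within-tool action decoding and cross-tool goal decoding.
#'
#' @param subject A subject as returned by [simulate_subject()].
#' @param phases Phases to decode (default planning and execution).
#' @param shrinkage Passed to [lda_fit_predict()].
#' @param seed Seed for trial balancing.
#' @param error_trials Optional per-run error-trial lists passed to
#'   [build_design_matrix()].
#' @return data.frame with one row per ROI x phase x comparison: columns
#'   `subject`, `roi`, `phase`, `comparison`, `accuracy`, `n_folds`.
#' @export
decode_subject <- function(subject, phases = c("planning", "execution"),
                           shrinkage = "lw", seed = 1, error_trials = NULL) {
  design <- build_design_matrix(subject$schedules, error_trials = error_trials)
  rois <- names(subject$data)
  Y_all <- do.call(cbind, lapply(rois, function(roi) {
    do.call(rbind, lapply(subject$data[[roi]], function(ts) t(ts$data)))
  }))
  n_vox <- vapply(rois, function(roi) nrow(subject$data[[roi]][[1]]$data),
                  integer(1))
  col_end <- cumsum(n_vox)
  col_start <- col_end - n_vox + 1
  fit_all <- fit_glm_ols(Y_all, design)
  rows <- list()
  for (roi in rois) {
    ri <- match(roi, rois)
    fit <- fit_all
    fit$coefficients <- fit_all$coefficients[, col_start[ri]:col_end[ri],
                                             drop = FALSE]
    for (ph in phases) {
      bp <- extract_phase_patterns(fit, ph, roi_name = roi,
                                   subject_id = subject$subject_id)
      bp <- balance_trials(bp, seed = derive_seed(seed, 29L, match(roi, names(subject$data))))
      folds <- make_loro_folds(unique(bp$labels$run))
      for (res in list(decode_within_tool_action(bp, folds, shrinkage),
                       decode_cross_tool_goal(bp, folds, shrinkage))) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subject$subject_id, roi = roi, phase = ph,
          comparison = res$comparison, accuracy = res$accuracy,
          n_folds = length(res$per_fold), stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate and decode a whole study
#'
#' Runs [simulate_subject()] and [decode_subject()] for `n_subjects`
#' subjects under one master seed and stacks the per-subject decoding
#' tables.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param seed Master seed.
#' @param profile,noise,n_voxels,rois,n_runs Passed to [simulate_subject()].
#' @param phases,shrinkage Passed to [decode_subject()].
#' @return data.frame of per-subject decoding accuracies.
#' @export
simulate_and_decode_study <- function(n_subjects = 17, seed = 1,
                                      profile = default_encoding_profile(),
                                      noise = noise_spec(), n_voxels = 100,
                                      rois = mvpa_rois(), n_runs = 8,
                                      phases = c("planning", "execution"),
                                      shrinkage = "lw") {
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    sub <- simulate_subject(s, seed, profile, noise, n_voxels, rois, n_runs)
    decode_subject(sub, phases, shrinkage, seed = derive_seed(seed, 31L, s))
  }))
}
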