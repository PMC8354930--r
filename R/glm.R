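#' Canonical double-gamma haemodynamic response function
#'
#' The standard difference-of-gammas impulse response (peak near 5 s,
#' undershoot near 15 s), sampled on a regular grid over 32 s and scaled to
#' unit peak.
#'
#' @param dt Sampling interval in seconds, `0 < dt <= 2`.
#' @param duration Kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma shape parameters (defaults 6 and
#'   16, rate 1/s).
#' @param undershoot_ratio Amplitude of the undershoot gamma relative to the
#'   peak gamma (default 1/6).
#' @return Numeric vector of kernel values at `seq(0, duration, by = dt)`,
#'   with `max(kernel) == 1`.
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, undershoot_ratio = 1 / 6) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 2) {
    stop("`dt` must be a single value in (0, 2]")
  }
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / max(h)
}

# Regressor cache: trial onsets sit on a fixed grid shared by every run and
# subject, so each distinct (onsets, durations, n_volumes, tr, dt) regressor
# is computed once per session.
.reg_cache <- new.env(parent = emptyenv())

convolve_events_cached <- function(onsets, durations, n_volumes, tr, dt = 0.1,
                                   kernel = canonical_hrf(dt)) {
  key <- paste(c(round(onsets, 4), "|", round(durations, 4), n_volumes, tr, dt),
               collapse = ",")
  hit <- .reg_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- convolve_events(onsets, durations, n_volumes, tr, dt, kernel)
  .reg_cache[[key]] <- val
  val
}

# Convolve boxcar events with the HRF on a microtime grid and sample at
# volume acquisition times. Returns a length-n_volumes vector on the
# continuous-convolution scale (sum x dt).
convolve_events <- function(onsets, durations, n_volumes, tr, dt = 0.1,
                            kernel = canonical_hrf(dt)) {
  if (any(durations <= 0)) stop("event durations must be positive")
  total <- n_volumes * tr
  grid <- seq(0, total - dt, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    on <- grid >= onsets[i] & grid < onsets[i] + durations[i]
    box[on] <- box[on] + 1
  }
  conv <- stats::convolve(box, rev(kernel), type = "open")[seq_along(grid)] * dt
  idx <- round(seq(0, n_volumes - 1) * tr / dt) + 1
  conv[idx]
}

# Discrete-cosine high-pass basis (periods above `cutoff` seconds) for a run
# of n volumes; excludes the constant term.
dct_highpass_basis <- function(n_volumes, tr, cutoff = 128) {
  k_max <- floor(2 * n_volumes * tr / cutoff)
  if (k_max < 1) return(matrix(0, n_volumes, 0))
  t <- seq_len(n_volumes) - 1
  sapply(seq_len(k_max), function(k) {
    cos(pi * (2 * t + 1) * k / (2 * n_volumes))
  })
}

#' Build the trial-wise (beta-series) design matrix
#'
#' One regressor of interest per trial and phase (cue 1 s, planning 9 s,
#' execution 2.5 s boxcars convolved with the canonical HRF), runs
#' block-diagonal, in a single least-squares-all model: 16 trials x 3 phases
#' x 8 runs = 384 regressors of interest for the full design. Per-run
#' nuisance columns comprise an intercept, a discrete-cosine high-pass basis
#' (cutoff 128 s) and optional motion parameters; trials flagged as errors
#' are moved to a pooled per-run error regressor of no interest.
#'
#' @param schedules List of `run_schedule` objects (one per run).
#' @param motion Optional list of per-run volumes x 6 motion-parameter
#'   matrices appended as nuisance columns.
#' @param hp_cutoff High-pass cutoff in seconds (default 128).
#' @param dt Microtime resolution for the convolution (default 0.1 s).
#' @param error_trials Optional list (same length as `schedules`) of
#'   integer vectors of `trial_index_in_run` values to treat as errors.
#' @param planning_as_impulse If `TRUE`, model planning as a zero-ish
#'   (0.1 s) event instead of the full 9 s boxcar (default `FALSE`).
#' @return A `design_matrix` object: list with `matrix` (volumes x columns),
#'   `labels` (data.frame with `type` "interest"/"nuisance", `run`, `trial`,
#'   `phase`, `condition`, `action`, `tool`, `tag`), `interest_count`,
#'   `run_rows` (per-run row index list) and `tr`.
#' @export
build_design_matrix <- function(schedules, motion = NULL, hp_cutoff = 128,
                                dt = 0.1, error_trials = NULL,
                                planning_as_impulse = FALSE) {
  stopifnot(length(schedules) >= 1)
  kernel <- canonical_hrf(dt)
  n_runs <- length(schedules)
  vols <- vapply(schedules, run_volume_count, integer(1))
  total_vols <- sum(vols)
  row_offsets <- c(0, cumsum(vols))
  cols <- list()
  lab_type <- lab_phase <- lab_cond <- lab_action <- lab_tool <- lab_tag <- character(0)
  lab_run <- lab_trial <- integer(0)

  add_col <- function(rows, values, type, run, trial = NA_integer_,
                      phase = NA_character_, condition = NA_character_,
                      action = NA_character_, tool = NA_character_, tag) {
    col <- numeric(total_vols)
    col[rows] <- values
    cols[[length(cols) + 1]] <<- col
    lab_type[length(cols)] <<- type; lab_run[length(cols)] <<- run
    lab_trial[length(cols)] <<- trial; lab_phase[length(cols)] <<- phase
    lab_cond[length(cols)] <<- condition; lab_action[length(cols)] <<- action
    lab_tool[length(cols)] <<- tool; lab_tag[length(cols)] <<- tag
  }

  for (r in seq_len(n_runs)) {
    sch <- schedules[[r]]
    nv <- vols[r]
    rows <- row_offsets[r] + seq_len(nv)
    errs <- if (!is.null(error_trials)) error_trials[[r]] else integer(0)
    err_col <- numeric(nv)
    trials <- sch$trials
    for (i in seq_len(nrow(trials))) {
      for (ph in phase_names()) {
        onset <- trials[[paste0(ph, "_onset")]][i]
        dur <- trials[[paste0(ph, "_duration")]][i]
        if (planning_as_impulse && ph == "planning") dur <- 0.1
        reg <- convolve_events_cached(onset, dur, nv, sch$tr, dt, kernel)
        if (trials$trial_index_in_run[i] %in% errs) {
          err_col <- err_col + reg
        } else {
          add_col(rows, reg, "interest", sch$run_index,
                  trials$trial_index_in_run[i], ph, trials$condition[i],
                  trials$action[i], trials$tool[i], tag = "trial")
        }
      }
    }
    if (any(err_col != 0)) {
      add_col(rows, err_col, "nuisance", sch$run_index, tag = "error")
    }
    add_col(rows, rep(1, nv), "nuisance", sch$run_index, tag = "intercept")
    dct <- dct_highpass_basis(nv, sch$tr, hp_cutoff)
    for (k in seq_len(ncol(dct))) {
      add_col(rows, dct[, k], "nuisance", sch$run_index, tag = paste0("dct", k))
    }
    if (!is.null(motion)) {
      mo <- motion[[r]]
      if (nrow(mo) != nv) stop("motion matrix for run ", sch$run_index,
                               " has ", nrow(mo), " rows, expected ", nv)
      for (k in seq_len(ncol(mo))) {
        add_col(rows, mo[, k], "nuisance", sch$run_index,
                tag = paste0("motion", k))
      }
    }
  }

  X <- do.call(cbind, cols)
  lab <- data.frame(type = lab_type, run = lab_run, trial = lab_trial,
                    phase = lab_phase, condition = lab_cond,
                    action = lab_action, tool = lab_tool, tag = lab_tag,
                    stringsAsFactors = FALSE)
  interest <- lab$type == "interest"
  if (any(colSums(abs(X[, interest, drop = FALSE])) == 0)) {
    stop("design contains an all-zero regressor of interest")
  }
  structure(
    list(matrix = X, labels = lab, interest_count = sum(interest),
         run_rows = lapply(seq_len(n_runs),
                           function(r) row_offsets[r] + seq_len(vols[r])),
         tr = schedules[[1]]$tr),
    class = "design_matrix"
  )
}

#' Ordinary least-squares fit of the trial-wise GLM
#'
#' @param Y Data: a volumes x voxels matrix, or a list of `roi_time_series`
#'   objects (one per run, voxels x volumes) which are concatenated in run
#'   order.
#' @param design A `design_matrix`.
#' @return A `glm_fit` object: list with `coefficients` (columns x voxels),
#'   `sigma2` (residual variance per voxel), `df_residual`, and the design's
#'   `labels`.
#' @export
fit_glm_ols <- function(Y, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.list(Y) && !is.matrix(Y)) {
    Y <- do.call(rbind, lapply(Y, function(ts) {
      stopifnot(inherits(ts, "roi_time_series"))
      t(ts$data)
    }))
  }
  X <- design$matrix
  if (nrow(Y) != nrow(X)) {
    stop("data has ", nrow(Y), " volumes but the design expects ", nrow(X))
  }
  # The session design is identical across subjects (fixed trial timing), so
  # the Cholesky factor of X'X is cached on a content key.
  key <- paste("chol", nrow(X), ncol(X), sum(X), sum(X^2), sum(X[, 1] * X[, ncol(X)]))
  ch <- .reg_cache[[key]]
  if (is.null(ch)) {
    xtx <- crossprod(X)
    ch <- tryCatch(chol(xtx), error = function(e) NULL)
    if (!is.null(ch) &&
        min(diag(ch))^2 < 1e-10 * max(diag(xtx))) ch <- NULL
    if (!is.null(ch)) .reg_cache[[key]] <- ch
  }
  if (is.null(ch)) {
    qx <- qr(X)
    bad <- qx$pivot[seq(qx$rank + 1, length.out = ncol(X) - qx$rank)]
    lab <- design$labels[bad, ]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(paste0(ifelse(lab$type == "interest",
                             paste0("trial", lab$trial, ".", lab$phase),
                             lab$tag), "/run", lab$run), collapse = ", "))
  }
  beta <- backsolve(ch, backsolve(ch, crossprod(X, Y), transpose = TRUE))
  res <- Y - X %*% beta
  dfres <- nrow(Y) - ncol(X)
  structure(
    list(coefficients = beta, sigma2 = colSums(res^2) / dfres,
         df_residual = dfres, labels = design$labels),
    class = "glm_fit"
  )
}

#' Extract phase-specific trial patterns from a GLM fit
#'
#' Restricts the beta-series coefficients to the regressors of interest of
#' one trial phase, yielding the trials x voxels pattern matrix used for
#' decoding, with trial labels carried through. Error trials never appear
#' (they are nuisance regressors in the design).
#'
#' @param fit A `glm_fit`.
#' @param phase One of "planning", "execution", "cue".
#' @param roi_name,subject_id Optional annotations stored on the result.
#' @return A `beta_patterns` object: list with `patterns` (trials x voxels)
#'   and `labels` (data.frame `run`, `trial`, `condition`, `action`, `tool`,
#'   `phase`).
#' @export
extract_phase_patterns <- function(fit, phase, roi_name = NA_character_,
                                   subject_id = NA_character_) {
  stopifnot(inherits(fit, "glm_fit"))
  phase <- match.arg(phase, c("planning", "execution", "cue"))
  sel <- fit$labels$type == "interest" & fit$labels$phase == phase
  structure(
    list(patterns = fit$coefficients[sel, , drop = FALSE],
         labels = fit$labels[sel, c("run", "trial", "condition", "action",
                                    "tool", "phase")],
         roi_name = roi_name, subject_id = subject_id),
    class = "beta_patterns"
  )
}
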