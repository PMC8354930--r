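# Synthetic BOLD generator. The forward model mirrors the assumptions of the
# analysis: every trial phase contributes (boxcar x HRF) responses whose
# multivoxel amplitude pattern carries (a) a tool-specific action code and
# (b) a tool-invariant goal code, on top of AR(1) noise and slow drift.

#' The eight tool-network ROIs used for decoding
#' @return Character vector of ROI names.
#' @export
mvpa_rois <- function() {
  c("pMTG", "SMG", "PMv", "aIPS", "PMd", "SPOC", "SPL", "M1")
}

#' Default ROI-by-phase encoding profile
#'
#' Encodes which region carries action and goal information in which trial
#' phase, with one gain per (ROI, phase, code). The default map: action
#' information in every ROI at execution and in all but M1 at planning; a
#' tool-invariant goal code in pMTG, aIPS, SPL and SPOC at planning and in
#' pMTG, aIPS, SPL, SMG and PMv at execution. The cue phase carries no
#' condition information. Gain magnitudes are calibration choices (see the
#' methods vignette), scaled so that default decoding sits mid-range rather
#' than at ceiling under the default noise model.
#'
#' @param action_gain Amplitude of the action code where present (applies
#'   to execution-phase patterns).
#' @param goal_gain Amplitude of the goal code where present (execution
#'   phase).
#' @param planning_scale Multiplier applied to both gains at the planning
#'   phase. The 9-s planning regressor carries far more energy than the
#'   2.5-s execution regressor, so equal pattern amplitudes would make
#'   planning betas much easier to decode; the default rescaling equates
#'   the two phases' decodability under the default noise model.
#' @return An `encoding_profile`: data.frame with columns `roi`, `phase`,
#'   `action_gain`, `goal_gain` (one row per ROI x phase, all three phases).
#' @export
default_encoding_profile <- function(action_gain = 0.5, goal_gain = 0.55,
                                     planning_scale = 0.35) {
  rois <- mvpa_rois()
  grid <- expand.grid(roi = rois, phase = phase_names(),
                      stringsAsFactors = FALSE)
  grid$action_gain <- 0
  grid$goal_gain <- 0
  plan_action <- setdiff(rois, "M1")
  exec_action <- rois
  plan_goal <- c("pMTG", "aIPS", "SPL", "SPOC")
  exec_goal <- c("pMTG", "aIPS", "SPL", "SMG", "PMv")
  sel <- function(phase, rois_on) grid$phase == phase & grid$roi %in% rois_on
  grid$action_gain[sel("planning", plan_action)] <- action_gain * planning_scale
  grid$action_gain[sel("execution", exec_action)] <- action_gain
  grid$goal_gain[sel("planning", plan_goal)] <- goal_gain * planning_scale
  grid$goal_gain[sel("execution", exec_goal)] <- goal_gain
  structure(grid, class = c("encoding_profile", "data.frame"))
}

#' Null encoding profile (no condition information anywhere)
#' @return An `encoding_profile` with all gains zero.
#' @export
null_encoding_profile <- function() default_encoding_profile(0, 0)

profile_gains <- function(profile, roi, phase) {
  row <- profile[profile$roi == roi & profile$phase == phase, ]
  if (nrow(row) == 0) return(list(action_gain = 0, goal_gain = 0))
  list(action_gain = row$action_gain[1], goal_gain = row$goal_gain[1])
}

#' Noise specification for synthetic BOLD
#'
#' @param sigma Marginal standard deviation of the AR(1) noise (signal
#'   units; must be > 0 unless exactly 0 for noiseless data).
#' @param ar1_rho Lag-1 autocorrelation in `[0, 1)`.
#' @param drift_amplitude Standard deviation of the random coefficients on
#'   the slow cosine drift terms (periods above 128 s).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma = 1, ar1_rho = 0.3, drift_amplitude = 1) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("`ar1_rho` must be in [0, 1)")
  if (drift_amplitude < 0) stop("`drift_amplitude` must be >= 0")
  structure(list(sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude), class = "noise_spec")
}

#' Draw the condition-specific voxel patterns for one ROI and phase
#'
#' Each of the four conditions gets the pattern
#' `action_gain * a(action, tool) + goal_gain * g(action)`, where the four
#' `a` vectors are mutually orthogonal random unit vectors (a tool-specific
#' action code: distinct even for the same action performed with different
#' tools) and `g(move) = +g0`, `g(use) = -g0` is a single unit vector shared
#' across tools (the tool-invariant goal code). With `goal_gain = 0` nothing
#' transfers across tools by construction; with `action_gain = 0` the two
#' tools of an action become indistinguishable.
#'
#' @param profile An `encoding_profile`.
#' @param roi,phase Which cell of the profile to realise.
#' @param n_voxels Number of voxels (>= 2).
#' @param seed Integer seed (patterns are redrawn per subject in
#'   [simulate_subject()]).
#' @param gain_scale Optional length-2 multiplier `(action, goal)` applied
#'   on top of the profile gains (used for between-subject jitter).
#' @return Named list mapping condition label to a length-`n_voxels`
#'   pattern vector.
#' @export
make_condition_patterns <- function(profile, roi, phase, n_voxels, seed,
                                    gain_scale = c(1, 1)) {
  if (n_voxels < 2) stop("`n_voxels` must be at least 2")
  g <- profile_gains(profile, roi, phase)
  ag <- g$action_gain * gain_scale[1]
  gg <- g$goal_gain * gain_scale[2]
  basis <- local_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(n_voxels * 5), n_voxels, 5)))
  })
  conds <- enumerate_conditions()
  out <- vector("list", nrow(conds))
  names(out) <- conds$condition
  for (i in seq_len(nrow(conds))) {
    goal_sign <- if (conds$action[i] == "move") 1 else -1
    out[[i]] <- ag * basis[, i] + gg * goal_sign * basis[, 5]
  }
  out
}

# Stationary AR(1) noise matrix (n_voxels x n_volumes), marginal sd sigma.
ar1_noise <- function(n_voxels, n_volumes, sigma, rho) {
  if (sigma == 0) return(matrix(0, n_voxels, n_volumes))
  e <- matrix(0, n_voxels, n_volumes)
  e[, 1] <- stats::rnorm(n_voxels, sd = sigma)
  innov_sd <- sigma * sqrt(1 - rho^2)
  for (t in seq_len(n_volumes)[-1]) {
    e[, t] <- rho * e[, t - 1] + stats::rnorm(n_voxels, sd = innov_sd)
  }
  e
}

#' Simulate one ROI's voxel time series for one run
#'
#' The signal is the sum over conditions and phases of the condition's
#' boxcar-convolved-HRF regressor times its voxel pattern; the noise is
#' stationary AR(1) plus slow cosine drift, independent across voxels.
#'
#' @param schedule A `run_schedule`.
#' @param patterns List over phases (`cue`, `planning`, `execution`) of
#'   condition-to-pattern maps as returned by [make_condition_patterns()].
#' @param noise A `noise_spec`.
#' @param seed Integer seed.
#' @param subject_id,roi_name Annotations stored on the result.
#' @param dt Microtime resolution for the convolution (default 0.1 s).
#' @return A `roi_time_series`: list with `data` (voxels x volumes), `tr`,
#'   `subject_id`, `roi_name`, `run_index`.
#' @export
simulate_roi_run <- function(schedule, patterns, noise = noise_spec(),
                             seed = 1, subject_id = NA_character_,
                             roi_name = NA_character_, dt = 0.1) {
  stopifnot(inherits(schedule, "run_schedule"))
  nv_list <- unlist(lapply(patterns, function(p) vapply(p, length, integer(1))))
  if (length(unique(nv_list)) != 1) {
    stop("all condition patterns must have the same voxel count")
  }
  n_voxels <- nv_list[[1]]
  n_volumes <- run_volume_count(schedule)
  kernel <- canonical_hrf(dt)
  conds <- enumerate_conditions()$condition
  Y <- matrix(0, n_voxels, n_volumes)
  for (ph in phase_names()) {
    ev <- trial_phase_events(schedule, ph)
    regs <- vapply(seq_len(nrow(ev)), function(i) {
      convolve_events_cached(ev$onset[i], ev$duration[i], n_volumes,
                             schedule$tr, dt, kernel)
    }, numeric(n_volumes))
    P <- vapply(schedule$trials$condition,
                function(cd) patterns[[ph]][[cd]], numeric(n_voxels))
    Y <- Y + P %*% t(regs)
  }
  local_seed(seed, {
    Y <- Y + ar1_noise(n_voxels, n_volumes, noise$sigma, noise$ar1_rho)
    if (noise$drift_amplitude > 0) {
      dct <- dct_highpass_basis(n_volumes, schedule$tr, 128)
      if (ncol(dct) > 0) {
        coefs <- matrix(stats::rnorm(n_voxels * ncol(dct),
                                     sd = noise$drift_amplitude),
                        n_voxels, ncol(dct))
        Y <- Y + coefs %*% t(dct)
      }
    }
  })
  structure(
    list(data = Y, tr = schedule$tr, subject_id = subject_id,
         roi_name = roi_name, run_index = schedule$run_index),
    class = "roi_time_series"
  )
}

#' Simulate a whole subject: schedules plus all ROI runs
#'
#' Pattern vectors are redrawn per subject and profile gains are jittered
#' multiplicatively by +/-20% per subject x ROI x phase, giving the
#' between-subject variability that group-level random-effects tests assume.
#' All randomness derives from `seed` and `subject_index`.
#'
#' @param subject_index Integer (1-based) subject label.
#' @param seed Master seed of the study.
#' @param profile An `encoding_profile`.
#' @param noise A `noise_spec`.
#' @param n_voxels Voxels per ROI (default 100).
#' @param rois ROI names (default the eight tool-network ROIs).
#' @param n_runs Number of runs (default 8).
#' @param gain_jitter Half-width of the uniform multiplicative jitter on the
#'   gains (default 0.2; set 0 to disable).
#' @return List with `subject_id`, `schedules`, and `data`:
#'   `data[[roi]][[run]]` is a `roi_time_series`.
#' @export
simulate_subject <- function(subject_index, seed, profile = default_encoding_profile(),
                             noise = noise_spec(), n_voxels = 100,
                             rois = mvpa_rois(), n_runs = 8,
                             gain_jitter = 0.2) {
  subject_id <- sprintf("sub-%02d", subject_index)
  schedules <- build_session_schedules(derive_seed(seed, 7L, subject_index),
                                       n_runs = n_runs)
  data <- vector("list", length(rois))
  names(data) <- rois
  for (ri in seq_along(rois)) {
    roi <- rois[ri]
    patterns <- vector("list", 3)
    names(patterns) <- phase_names()
    for (pi in seq_along(phase_names())) {
      ph <- phase_names()[pi]
      jseed <- derive_seed(seed, 11L, subject_index, ri, pi)
      scale <- local_seed(jseed, stats::runif(2, 1 - gain_jitter, 1 + gain_jitter))
      patterns[[ph]] <- make_condition_patterns(
        profile, roi, ph, n_voxels,
        seed = derive_seed(seed, 13L, subject_index, ri, pi),
        gain_scale = scale
      )
    }
    data[[roi]] <- lapply(seq_len(n_runs), function(r) {
      simulate_roi_run(schedules[[r]], patterns, noise,
                       seed = derive_seed(seed, 17L, subject_index, ri, r),
                       subject_id = subject_id, roi_name = roi)
    })
  }
  list(subject_id = subject_id, subject_index = subject_index,
       schedules = schedules, data = data)
}
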