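# Three-node effective-connectivity engine: bilinear neural dynamics with a
# balloon-Windkessel observation model (forward integration in C++), MAP
# inversion of the coupling parameters with a Laplace approximation to the
# model evidence, and random-effects Bayesian model selection.

#' Node order of the connectivity network
#' @return `c("pMTG", "aIPS", "PMv")` — auditory task input enters at pMTG.
#' @export
dcm_nodes <- function() c("pMTG", "aIPS", "PMv")

#' Fixed haemodynamic (balloon-Windkessel) parameters
#'
#' Literature-standard constants, held fixed during inversion so that only
#' the neural coupling (A, B, C) is estimated: signal decay `kappa`
#' (1/s), flow feedback `gamma` (1/s), mean transit time `tau` (s), vessel
#' stiffness `alpha`, resting oxygen extraction `rho`, resting venous
#' volume fraction `V0`.
#'
#' @return Named numeric vector.
#' @export
default_hemo_params <- function() {
  c(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32, rho = 0.4,
    V0 = 0.04)
}

#' Construct a DCM model definition
#'
#' @param model_id Integer label (1-15 in the shipped space).
#' @param b_support 3x3 logical matrix: which directed connections the task
#'   input may modulate (off-diagonal only).
#' @return A `dcm_model`: list with `nodes`, `model_id`, `b_support`,
#'   `input_node` (pMTG).
#' @export
dcm_model <- function(model_id, b_support) {
  b_support <- matrix(as.logical(b_support), 3, 3)
  if (any(diag(b_support))) stop("modulation of self-connections is not allowed")
  structure(list(nodes = dcm_nodes(), model_id = as.integer(model_id),
                 b_support = b_support, input_node = "pMTG"),
            class = "dcm_model")
}

#' Load the 15-model modulatory space
#'
#' Reads the shipped (user-replaceable) fixture table enumerating which of
#' the six directed inter-node connections the task modulates in each
#' model. Model 1 modulates all six (forward and backward); the remaining
#' models are the non-empty combinations of ventral-to-dorsal,
#' dorsal-to-ventral and within-dorsolateral modulation elements. The exact
#' composition of models 2-15 is an approximation encoded in the fixture
#' (see the methods vignette).
#'
#' @param path Fixture path; defaults to the table shipped with the
#'   package.
#' @return List of 15 `dcm_model` objects.
#' @export
build_model_space <- function(path = system.file("extdata",
                                                 "dcm_model_space.tsv",
                                                 package = "toolnet")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("pMTG_to_aIPS", "pMTG_to_PMv", "aIPS_to_pMTG", "PMv_to_pMTG",
            "aIPS_to_PMv", "PMv_to_aIPS")
  if (!all(c("model_id", cols) %in% names(tab))) {
    stop("malformed model-space fixture: expected columns model_id, ",
         paste(cols, collapse = ", "))
  }
  nodes <- dcm_nodes()
  lapply(seq_len(nrow(tab)), function(i) {
    b <- matrix(FALSE, 3, 3, dimnames = list(nodes, nodes))
    for (cn in cols) {
      if (tab[[cn]][i] != 0) {
        parts <- strsplit(cn, "_to_")[[1]]
        b[parts[2], parts[1]] <- TRUE  # row = target, column = source
      }
    }
    if (!any(b)) stop("malformed model-space fixture: model ",
                      tab$model_id[i], " modulates nothing")
    dcm_model(tab$model_id[i], b)
  })
}

#' Task and driving input timecourses for the DCM
#'
#' The driving input is the auditory instruction stream entering pMTG: the
#' 1-s verbal cue of every trial plus the brief go signal at execution
#' onset of every trial. The task (modulatory) input is the boxcar of
#' execution-phase grasp-to-use events only, so non-use executions provide
#' the unmodulated propagation baseline that identifies the modulatory
#' weights.
#'
#' @param schedule A `run_schedule`.
#' @param dt Integration step (default 0.05 s).
#' @param go_duration Duration of the go beep in seconds (default 0.5).
#' @return List with `u_task`, `u_drive` (vectors on the dt grid), `dt`,
#'   `tr` and `n_volumes`.
#' @export
dcm_inputs_from_schedule <- function(schedule, dt = 0.05, go_duration = 0.5) {
  n_volumes <- run_volume_count(schedule)
  total <- n_volumes * schedule$tr
  grid <- seq(0, total - dt, by = dt)
  box <- function(onsets, durations) {
    u <- numeric(length(grid))
    for (i in seq_along(onsets)) {
      u[grid >= onsets[i] & grid < onsets[i] + durations[i]] <- 1
    }
    u
  }
  cue <- trial_phase_events(schedule, "cue")
  ex_all <- trial_phase_events(schedule, "execution")
  use <- schedule$trials$action == "use"
  ex_use <- ex_all[use, ]
  u_drive <- pmin(1, box(cue$onset, cue$duration) +
                     box(ex_all$onset, rep(go_duration, nrow(ex_all))))
  list(u_task = box(ex_use$onset, ex_use$duration), u_drive = u_drive,
       dt = dt, tr = schedule$tr, n_volumes = n_volumes)
}

check_A_stable <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  mx <- max(Re(ev))
  if (mx >= 0) {
    stop("unstable intrinsic coupling: eigenvalue with real part ",
         signif(mx, 4), " >= 0 at rest")
  }
  invisible(mx)
}

#' Integrate the bilinear neural + haemodynamic forward model
#'
#' Solves `dz/dt = (A + u_task B) z + C u_drive` together with the
#' balloon-Windkessel equations per node by a fixed-step 4th-order
#' Runge-Kutta scheme, then returns the BOLD observation downsampled to the
#' TR grid.
#'
#' @param A 3x3 intrinsic coupling matrix (1/s; negative diagonal,
#'   stable at rest).
#' @param B 3x3 modulatory matrix (applied when `u_task` is on).
#' @param C Length-3 driving-input weights (nonzero only at pMTG in the
#'   shipped models).
#' @param u List from [dcm_inputs_from_schedule()] (or same shape).
#' @param hemo Haemodynamic constants, see [default_hemo_params()].
#' @param return_neural Also return the neural states at the sampled times.
#' @return Matrix `n_volumes x 3` of BOLD signal (columns pMTG, aIPS, PMv);
#'   if `return_neural`, a list with `bold` and `neural`.
#' @export
integrate_bilinear_dcm <- function(A, B, C, u, hemo = default_hemo_params(),
                                   return_neural = FALSE) {
  check_A_stable(A)
  keep <- round(u$tr / u$dt)
  out <- dcm_integrate_cpp(A, B, as.numeric(C), u$u_task, u$u_drive, u$dt,
                           as.integer(keep), as.numeric(hemo),
                           return_neural)
  if (out$blowup) {
    ev <- eigen(A + B, only.values = TRUE)$values
    stop("state blow-up during integration (max Re eigenvalue of A+B = ",
         signif(max(Re(ev)), 4), ")")
  }
  colnames(out$bold) <- dcm_nodes()
  if (return_neural) {
    colnames(out$neural) <- dcm_nodes()
    list(bold = out$bold, neural = out$neural)
  } else {
    out$bold
  }
}

#' First eigenvariate of an ROI's voxel time series
#'
#' Summarises a voxels x volumes matrix by the projection of the
#' (voxel-mean-centred) data onto its first principal direction,
#' sign-aligned so that the mean voxel loading is positive, and scaled to
#' unit variance.
#'
#' @param data Voxels x volumes numeric matrix (>= 1 voxel, >= 2 volumes).
#' @return Numeric timecourse of length `ncol(data)`.
#' @export
first_eigenvariate <- function(data) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop("need at least 2 volumes")
  X <- t(data)                       # volumes x voxels
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < .Machine$double.eps * 100)) {
    stop("degenerate input: time series are constant")
  }
  sv <- svd(X, nu = 1, nv = 1)
  e <- sv$u[, 1]
  if (mean(sv$v[, 1]) < 0) e <- -e
  e / stats::sd(e)
}
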