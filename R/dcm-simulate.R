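# Synthetic DCM datasets: forward-simulated node timecourses from a known
# coupling configuration, used to validate inversion and model selection.

#' Ground-truth coupling parameters for the full-modulation model
#'
#' A stable intrinsic network (self-decay -0.5 1/s, weak positive
#' inter-node coupling) whose six directed connections are all strengthened
#' while the grasp-to-use execution input is on, with the auditory stream
#' driving pMTG.
#'
#' @return List with matrices `A`, `B` and vector `C`.
#' @export
default_dcm_truth <- function() {
  nodes <- dcm_nodes()
  # asymmetric intrinsic couplings so the three nodes carry distinct
  # timecourses (symmetric coupling would make the modulated connections
  # mutually indistinguishable)
  A <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  diag(A) <- -0.5
  A["aIPS", "pMTG"] <- 0.25
  A["PMv", "pMTG"] <- 0.05
  A["pMTG", "aIPS"] <- 0.10
  A["pMTG", "PMv"] <- 0.05
  A["PMv", "aIPS"] <- 0.20
  A["aIPS", "PMv"] <- 0.05
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B["aIPS", "pMTG"] <- 0.35  # ventral -> dorsal forward
  B["PMv", "pMTG"] <- 0.30
  B["pMTG", "aIPS"] <- 0.25  # dorsal -> ventral backward
  B["pMTG", "PMv"] <- 0.20
  B["PMv", "aIPS"] <- 0.30   # within-dorsolateral
  B["aIPS", "PMv"] <- 0.25
  C <- c(pMTG = 1, aIPS = 0, PMv = 0)
  list(A = A, B = B, C = C)
}

#' Simulate a multi-subject DCM dataset from a known model
#'
#' Integrates the bilinear + haemodynamic forward model per subject, with
#' multiplicative +/-`jitter` between-subject variation of every nonzero
#' coupling entry, and adds white observation noise scaled so that each
#' node's signal-sd-to-noise-sd ratio equals `snr`.
#'
#' @param true_model A `dcm_model` giving the modulatory support; entries
#'   of `params$B` outside the support are zeroed.
#' @param params List with `A`, `B`, `C` (defaults
#'   [default_dcm_truth()]).
#' @param n_subjects Number of subjects (default 17).
#' @param snr Signal-to-noise ratio (sd of noiseless BOLD / sd of noise);
#'   `Inf` gives noiseless data. The default 20 is the package's "high
#'   SNR" validation condition, at which the model space is decisively
#'   discriminable; at substantially lower ratios the weakest modulation
#'   no longer repays its complexity cost and reduced models win.
#' @param seed Master seed.
#' @param schedule Run schedule defining the input streams (default: run 0
#'   of the standard session).
#' @param jitter Half-width of the uniform multiplicative parameter jitter
#'   (default 0.2).
#' @param dt Integration step (default 0.05 s).
#' @return List with `subjects` (each: `y` volumes x 3, `truth` = that
#'   subject's jittered A/B/C), `u`, `true_model`.
#' @export
simulate_dcm_dataset <- function(true_model, params = default_dcm_truth(),
                                 n_subjects = 17, snr = 20, seed = 1,
                                 schedule = build_run_schedule(0, seed),
                                 jitter = 0.2, dt = 0.05) {
  stopifnot(inherits(true_model, "dcm_model"))
  check_A_stable(params$A)
  if (any(params$C[-1] != 0)) {
    stop("the driving input must enter at pMTG only")
  }
  B <- params$B
  B[!true_model$b_support] <- 0
  u <- dcm_inputs_from_schedule(schedule, dt)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    jseed <- derive_seed(seed, 41L, s)
    local_seed(jseed, {
      jit <- function(M) {
        out <- M
        nz <- M != 0
        out[nz] <- M[nz] * stats::runif(sum(nz), 1 - jitter, 1 + jitter)
        out
      }
      As <- jit(params$A); diag(As) <- diag(params$A)  # keep decay fixed
      Bs <- jit(B); Cs <- jit(params$C)
      bold <- integrate_bilinear_dcm(As, Bs, Cs, u)
      y <- bold
      if (is.finite(snr)) {
        for (j in seq_len(ncol(y))) {
          y[, j] <- y[, j] + stats::rnorm(nrow(y),
                                          sd = stats::sd(bold[, j]) / snr)
        }
      }
      list(y = y, truth = list(A = As, B = Bs, C = Cs))
    })
  })
  list(subjects = subjects, u = u, true_model = true_model)
}

#' Fit every model of a space to every subject
#'
#' @param dataset Output of [simulate_dcm_dataset()] (or a list with the
#'   same shape built from real node timecourses).
#' @param model_space List of `dcm_model` (default the shipped 15).
#' @param ... Passed to [invert_dcm()].
#' @return List with `log_evidences` (subjects x models matrix) and `fits`
#'   (list of per-subject lists of `dcm_fit`).
#' @export
fit_model_space <- function(dataset, model_space = build_model_space(), ...) {
  n_sub <- length(dataset$subjects)
  lme <- matrix(NA_real_, n_sub, length(model_space),
                dimnames = list(NULL, paste0("model", vapply(model_space,
                  function(m) m$model_id, integer(1)))))
  fits <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    fits[[s]] <- lapply(model_space, function(m) {
      invert_dcm(dataset$subjects[[s]]$y, m, dataset$u, ...)
    })
    lme[s, ] <- vapply(fits[[s]], function(f) f$log_evidence, numeric(1))
  }
  list(log_evidences = lme, fits = fits)
}
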