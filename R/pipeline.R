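# End-to-end orchestration: one config, deterministic seeding, tabular
# outputs on disk. Each stage reads its upstream artifacts from `out_dir`,
# so stages can be re-run selectively.

#' Default pipeline configuration
#'
#' @param seed Master seed for every stage.
#' @param n_subjects Simulated subjects (default 17).
#' @param n_voxels Voxels per ROI (default 100).
#' @param action_gain,goal_gain Encoding-profile gains (defaults as in
#'   [default_encoding_profile()]).
#' @param sigma,ar1_rho,drift_amplitude Noise model, see [noise_spec()].
#' @param shrinkage LDA shrinkage (`"lw"` or a fraction).
#' @param fdr_q FDR level.
#' @param fdr_family `"all"` or `"per_phase"`.
#' @param dcm_snr Signal-to-noise ratio of the synthetic DCM data.
#' @param dcm_n_subjects Subjects in the DCM stage (default `n_subjects`).
#' @param bms_samples Monte Carlo draws for exceedance probabilities.
#' @param model_space_path Path to the modulatory-space fixture.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 17, n_voxels = 100,
                            action_gain = formals(default_encoding_profile)$action_gain,
                            goal_gain = formals(default_encoding_profile)$goal_gain,
                            sigma = 1, ar1_rho = 0.3, drift_amplitude = 1,
                            shrinkage = "lw", fdr_q = 0.05,
                            fdr_family = "all", dcm_snr = 20,
                            dcm_n_subjects = n_subjects, bms_samples = 1e6,
                            model_space_path = NULL) {
  structure(list(seed = seed, n_subjects = n_subjects, n_voxels = n_voxels,
                 action_gain = eval(action_gain), goal_gain = eval(goal_gain),
                 sigma = sigma, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude, shrinkage = shrinkage,
                 fdr_q = fdr_q, fdr_family = fdr_family, dcm_snr = dcm_snr,
                 dcm_n_subjects = dcm_n_subjects, bms_samples = bms_samples,
                 model_space_path = model_space_path),
            class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "glm", "decode", "group", "dcm", "bms", "report")
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop("stage `", needed_by, "` needs ", basename(path),
         " produced by stage `", stage, "`; run that stage first")
  }
  path
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` writes the per-run events tables; `glm`/`decode`
#' simulate each subject, fit the trial-wise GLM and write the decoding
#' accuracy table (the GLM is fitted within the decode stage, so `glm` is
#' subsumed by `decode`); `group` writes the group statistics and the
#' qualitative significance map; `dcm` simulates node timecourses from the
#' full-modulation ground truth and inverts the whole model space; `bms`
#' runs random-effects model selection on the log-evidence matrix;
#' `report` writes a run manifest. Identical configs give identical
#' outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @param stages Subset of [pipeline_stages()] to run (default all).
#' @return Invisibly, a named list of the file paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name, start) {
    message(sprintf("[toolnet] stage %-8s done in %.1f s", name,
                    proc.time()[["elapsed"]] - start))
  }
  profile <- default_encoding_profile(config$action_gain, config$goal_gain)
  noise <- noise_spec(config$sigma, config$ar1_rho, config$drift_amplitude)

  if ("simulate" %in% stages) {
    st <- proc.time()[["elapsed"]]
    schedules <- build_session_schedules(derive_seed(config$seed, 7L, 1L))
    paths$events <- write_events_tsv(schedules, file.path(out_dir, "events"))
    log_stage("simulate", st)
  }
  if (any(c("glm", "decode") %in% stages)) {
    st <- proc.time()[["elapsed"]]
    dec <- simulate_and_decode_study(
      n_subjects = config$n_subjects, seed = config$seed, profile = profile,
      noise = noise, n_voxels = config$n_voxels,
      shrinkage = config$shrinkage
    )
    paths$decoding <- file.path(out_dir, "decoding.csv")
    utils::write.csv(dec, paths$decoding, row.names = FALSE)
    log_stage("decode", st)
  }
  if ("group" %in% stages) {
    st <- proc.time()[["elapsed"]]
    dec_path <- require_artifact(file.path(out_dir, "decoding.csv"),
                                 "decode", "group")
    dec <- utils::read.csv(dec_path, stringsAsFactors = FALSE)
    grp <- group_decoding_stats(dec, q = config$fdr_q,
                                family = config$fdr_family)
    paths$group <- file.path(out_dir, "group_stats.csv")
    utils::write.csv(grp, paths$group, row.names = FALSE)
    paths$map <- file.path(out_dir, "significance_map.csv")
    utils::write.csv(significance_map(grp), paths$map, row.names = FALSE)
    log_stage("group", st)
  }
  if ("dcm" %in% stages) {
    st <- proc.time()[["elapsed"]]
    space <- if (is.null(config$model_space_path)) build_model_space()
             else build_model_space(config$model_space_path)
    dataset <- simulate_dcm_dataset(space[[1]],
                                    n_subjects = config$dcm_n_subjects,
                                    snr = config$dcm_snr,
                                    seed = derive_seed(config$seed, 43L))
    fit <- fit_model_space(dataset, space, outer = 2, use_zero_start = FALSE)
    paths$log_evidences <- file.path(out_dir, "log_evidences.csv")
    utils::write.csv(as.data.frame(fit$log_evidences),
                     paths$log_evidences, row.names = FALSE)
    win <- space[[1]]
    bnames <- paste0("B_", rep(dcm_nodes(), 3), "_from_",
                     rep(dcm_nodes(), each = 3))[which(win$b_support)]
    bpars <- t(vapply(fit$fits, function(fs) fs[[1]]$B[win$b_support],
                      numeric(sum(win$b_support))))
    colnames(bpars) <- bnames
    paths$parameters <- file.path(out_dir, "winning_model_parameters.csv")
    utils::write.csv(as.data.frame(bpars), paths$parameters,
                     row.names = FALSE)
    log_stage("dcm", st)
  }
  if ("bms" %in% stages) {
    st <- proc.time()[["elapsed"]]
    lme_path <- require_artifact(file.path(out_dir, "log_evidences.csv"),
                                 "dcm", "bms")
    lme <- as.matrix(utils::read.csv(lme_path))
    bms <- rfx_bms(lme, n_samples = config$bms_samples,
                   seed = derive_seed(config$seed, 47L))
    paths$bms <- file.path(out_dir, "bms.json")
    jsonlite::write_json(list(alpha = bms$alpha,
                              expected_r = bms$expected_r,
                              exceedance = bms$exceedance),
                         paths$bms, digits = NA)
    log_stage("bms", st)
  }
  if ("report" %in% stages) {
    st <- proc.time()[["elapsed"]]
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(package = "toolnet",
           version = as.character(utils::packageVersion("toolnet")),
           config = unclass(config), stages = stages),
      paths$manifest, auto_unbox = TRUE, digits = NA, null = "null"
    )
    log_stage("report", st)
  }
  message(sprintf("[toolnet] pipeline finished in %.1f s",
                  proc.time()[["elapsed"]] - t0))
  invisible(paths)
}
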