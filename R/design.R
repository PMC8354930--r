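#' Experimental conditions of the 2x2 pantomime design
#'
#' The delayed-pantomime task crosses the type of pantomimed action
#' (grasp-to-move vs grasp-to-use) with the pretended tool (scissors vs axe),
#' giving four conditions. The canonical order is fixed so that label
#' encodings are reproducible everywhere in the package.
#'
#' @return A data.frame with columns `action` ("move"/"use"), `tool`
#'   ("scissors"/"axe") and `condition` (the combined label
#'   `"<action>_<tool>"`), in canonical order: move_scissors, move_axe,
#'   use_scissors, use_axe.
#' @export
#' @examples
#' enumerate_conditions()
enumerate_conditions <- function() {
  df <- data.frame(
    action = c("move", "move", "use", "use"),
    tool = c("scissors", "axe", "scissors", "axe"),
    stringsAsFactors = FALSE
  )
  df$condition <- paste(df$action, df$tool, sep = "_")
  df
}

#' Default trial/run timing of the delayed-pantomime design
#'
#' Each trial is a verbal cue (1 s), a planning delay (9 s), pantomime
#' execution (2.5 s) and a fixed inter-trial interval (11.5 s): 24 s in
#' total. A run holds 16 trials between a 16 s initial and a 20 s final
#' baseline (420 s = 210 volumes at TR 2 s).
#'
#' @return Named list of timing constants in seconds (`cue`, `planning`,
#'   `execution`, `iti`, `baseline_pre`, `baseline_post`, `tr`).
#' @export
default_timing <- function() {
  list(cue = 1, planning = 9, execution = 2.5, iti = 11.5,
       baseline_pre = 16, baseline_post = 20, tr = 2)
}

phase_names <- function() c("cue", "planning", "execution")

#' Build the trial schedule for one functional run
#'
#' Lays out 16 trials (4 repetitions of each of the 4 conditions) in a
#' seeded pseudo-random order with mild counterbalancing: no more than
#' `max_consecutive` consecutive trials of the same condition. Trial onsets
#' follow the fixed timing grid (cue -> planning -> execution -> ITI).
#'
#' @param run_index Integer run label in `0:(n_runs-1)`.
#' @param seed Integer seed; identical `(run_index, seed)` gives an
#'   identical schedule.
#' @param timing Timing constants, see [default_timing()].
#' @param trials_per_condition Repetitions of each condition (default 4).
#' @param n_runs Total number of runs in the session (default 8); used only
#'   to validate `run_index`.
#' @param max_consecutive Maximum run-length of identical conditions in the
#'   permuted order (default 3); set to `Inf` for a fully random order.
#' @return A `run_schedule` object: list with `run_index`, `tr`,
#'   `baseline_pre`, `baseline_post`, `duration`, `timing` and a data.frame
#'   `trials` with one row per trial (condition, action, tool and the
#'   onset/duration of each phase, in seconds).
#' @export
build_run_schedule <- function(run_index, seed, timing = default_timing(),
                               trials_per_condition = 4, n_runs = 8,
                               max_consecutive = 3) {
  if (!is.numeric(run_index) || length(run_index) != 1 ||
      run_index != round(run_index) || run_index < 0 || run_index > n_runs - 1) {
    stop("`run_index` must be an integer in 0:", n_runs - 1)
  }
  conds <- enumerate_conditions()
  labels <- rep(conds$condition, each = trials_per_condition)
  order_seed <- derive_seed(seed, 101L, run_index)
  perm <- if (length(labels) == 0) character(0) else local_seed(order_seed, {
    ok <- FALSE
    out <- labels
    for (attempt in seq_len(1000)) {
      out <- sample(labels)
      r <- rle(out)$lengths
      if (max(r) <= max_consecutive) { ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy the consecutive-condition constraint")
    out
  })
  n_trials <- length(perm)
  trial_span <- timing$cue + timing$planning + timing$execution + timing$iti
  cue_onset <- timing$baseline_pre + (seq_len(n_trials) - 1) * trial_span
  trials <- if (n_trials == 0) {
    data.frame(trial_index_in_run = integer(0), condition = character(0),
               action = character(0), tool = character(0),
               cue_onset = numeric(0), cue_duration = numeric(0),
               planning_onset = numeric(0), planning_duration = numeric(0),
               execution_onset = numeric(0), execution_duration = numeric(0),
               iti_duration = numeric(0), stringsAsFactors = FALSE)
  } else data.frame(
    trial_index_in_run = seq_len(n_trials) - 1L,
    condition = perm,
    action = sub("_.*$", "", perm),
    tool = sub("^.*_", "", perm),
    cue_onset = cue_onset,
    cue_duration = timing$cue,
    planning_onset = cue_onset + timing$cue,
    planning_duration = timing$planning,
    execution_onset = cue_onset + timing$cue + timing$planning,
    execution_duration = timing$execution,
    iti_duration = timing$iti,
    stringsAsFactors = FALSE
  )
  duration <- timing$baseline_pre + n_trials * trial_span + timing$baseline_post
  structure(
    list(run_index = as.integer(run_index), trials = trials, tr = timing$tr,
         baseline_pre = timing$baseline_pre, baseline_post = timing$baseline_post,
         duration = duration, timing = timing),
    class = "run_schedule"
  )
}

#' Number of volumes acquired in a run
#'
#' @param schedule A `run_schedule`.
#' @return Integer volume count (`duration / tr`).
#' @export
run_volume_count <- function(schedule) {
  stopifnot(inherits(schedule, "run_schedule"))
  n <- schedule$duration / schedule$tr
  if (abs(n - round(n)) > 1e-9) {
    stop("run duration (", schedule$duration,
         " s) is not an integer multiple of TR (", schedule$tr, " s)")
  }
  as.integer(round(n))
}

#' Onsets and durations of one trial phase across a run
#'
#' @param schedule A `run_schedule`.
#' @param phase One of "cue", "planning", "execution".
#' @return data.frame with columns `onset` and `duration` (seconds), one row
#'   per trial, in trial order.
#' @export
trial_phase_events <- function(schedule, phase) {
  stopifnot(inherits(schedule, "run_schedule"))
  phase <- match.arg(phase, phase_names())
  tr <- schedule$trials
  data.frame(
    onset = tr[[paste0(phase, "_onset")]],
    duration = tr[[paste0(phase, "_duration")]]
  )
}

#' Write run schedules as BIDS-style events tables
#'
#' One tab-separated file per run with columns `onset`, `duration`,
#' `trial_type`, `phase`, `run`, rows ordered by onset.
#'
#' @param schedules List of `run_schedule` objects.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; files are named
#'   `<prefix>_run-<i>_events.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_events_tsv <- function(schedules, dir, prefix = "task-pantomime") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(schedules))
  for (i in seq_along(schedules)) {
    sch <- schedules[[i]]
    rows <- do.call(rbind, lapply(phase_names(), function(ph) {
      ev <- trial_phase_events(sch, ph)
      data.frame(onset = ev$onset, duration = ev$duration,
                 trial_type = sch$trials$condition, phase = ph,
                 run = sch$run_index, stringsAsFactors = FALSE)
    }))
    rows <- rows[order(rows$onset, rows$phase), ]
    path <- file.path(dir, sprintf("%s_run-%d_events.tsv", prefix, sch$run_index))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[i] <- path
  }
  invisible(paths)
}

#' Build the schedules for a whole session
#'
#' @param seed Integer master seed.
#' @param n_runs Number of runs (default 8).
#' @param ... Passed to [build_run_schedule()].
#' @return List of `run_schedule`, one per run index `0:(n_runs-1)`.
#' @export
build_session_schedules <- function(seed, n_runs = 8, ...) {
  lapply(seq_len(n_runs) - 1L, function(r) {
    build_run_schedule(r, seed = seed, n_runs = n_runs, ...)
  })
}
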