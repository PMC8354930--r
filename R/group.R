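# Group-level inference on decoding accuracies: one-tailed one-sample
# t-tests against chance (50%) with Benjamini-Yekutieli FDR control over
# the full ROI x comparison x phase family.

#' One-tailed one-sample t-test
#'
#' Upper-tailed test of the mean against `null_value` (chance = 0.5 for a
#' two-class decoder).
#'
#' @param values Numeric sample (length >= 2, finite).
#' @param null_value Null mean (default 0.5).
#' @return List with `t`, `df`, `p` (upper-tail) and `mean`.
#' @export
one_sample_t_one_tailed <- function(values, null_value = 0.5) {
  if (length(values) < 2 || !all(is.finite(values))) {
    stop("need at least 2 finite values")
  }
  if (stats::sd(values) == 0) {
    stop("degenerate sample: zero variance (all values equal ",
         values[1], ")")
  }
  ht <- stats::t.test(values, mu = null_value, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values))
}

#' Benjamini-Yekutieli FDR control
#'
#' Step-up procedure with the harmonic-sum correction
#' `c(m) = sum_{i=1..m} 1/i`, valid under arbitrary dependence among the
#' tests.
#'
#' @param pvals Numeric p-values in `(0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Logical mask of rejected hypotheses (empty input gives an empty
#'   mask).
#' @export
fdr_correct_by <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BY") <= q
}

#' Group inference over a decoding-accuracy table
#'
#' Tests each ROI x phase x comparison cell's subject accuracies against
#' chance (one-tailed) and applies BY-FDR jointly across the whole family
#' (by default all cells in the table; optionally per phase).
#'
#' @param decoding data.frame as returned by [decode_subject()] /
#'   [simulate_and_decode_study()].
#' @param q FDR level (default 0.05).
#' @param family `"all"` (one correction over every cell, the default) or
#'   `"per_phase"`.
#' @param null_value Chance level (default 0.5).
#' @return data.frame with one row per cell: `roi`, `phase`, `comparison`,
#'   `mean_accuracy`, `t`, `df`, `p`, `significant`.
#' @export
group_decoding_stats <- function(decoding, q = 0.05,
                                 family = c("all", "per_phase"),
                                 null_value = 0.5) {
  family <- match.arg(family)
  cells <- unique(decoding[, c("roi", "phase", "comparison")])
  cells <- cells[order(cells$phase, cells$comparison,
                       match(cells$roi, mvpa_rois())), ]
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- decoding$roi == cells$roi[i] & decoding$phase == cells$phase[i] &
      decoding$comparison == cells$comparison[i]
    tt <- one_sample_t_one_tailed(decoding$accuracy[sel], null_value)
    data.frame(roi = cells$roi[i], phase = cells$phase[i],
               comparison = cells$comparison[i], mean_accuracy = tt$mean,
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }))
  if (family == "all") {
    res$significant <- fdr_correct_by(res$p, q)
  } else {
    res$significant <- FALSE
    for (ph in unique(res$phase)) {
      sel <- res$phase == ph
      res$significant[sel] <- fdr_correct_by(res$p[sel], q)
    }
  }
  rownames(res) <- NULL
  res
}

#' Qualitative significance map from group results
#'
#' Restructures [group_decoding_stats()] output into a machine-readable map
#' (one row per ROI, logical columns per phase x comparison), the tabular
#' analogue of the study-summary figure.
#'
#' @param group_res Output of [group_decoding_stats()].
#' @return data.frame with columns `roi`, `action_planning`,
#'   `goal_planning`, `action_execution`, `goal_execution`.
#' @export
significance_map <- function(group_res) {
  rois <- unique(group_res$roi)
  get <- function(roi, ph, cmp) {
    sel <- group_res$roi == roi & group_res$phase == ph &
      group_res$comparison == cmp
    if (!any(sel)) NA else any(group_res$significant[sel])
  }
  data.frame(
    roi = rois,
    action_planning = vapply(rois, get, logical(1), "planning", "action"),
    goal_planning = vapply(rois, get, logical(1), "planning", "goal"),
    action_execution = vapply(rois, get, logical(1), "execution", "action"),
    goal_execution = vapply(rois, get, logical(1), "execution", "goal"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
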