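# Binary discrimination of severity-ordered groups from one score.
#
# Orientation is fixed throughout: the more severe group are the cases,
# lower scores indicate worse performance, and a score <= threshold is
# called positive. Sensitivity is the case true-positive rate and
# specificity the control true-negative rate under that rule.

#' Empirical ROC curve
#'
#' Sweeps the positivity threshold over the distinct pooled scores (plus a
#' \code{-Inf} sentinel) under the rule "score <= threshold is positive".
#' The curve runs from (fpr 0, tpr 0) to (1, 1) with both coordinates
#' nondecreasing.
#'
#' @param case_scores Scores of the more severe group.
#' @param control_scores Scores of the less severe group.
#' @return A data frame of class \code{roc_curve} with columns
#'   \code{threshold, tpr, fpr}.
#' @export
roc_curve <- function(case_scores, control_scores) {
  check_roc_input(case_scores, control_scores)
  thr <- c(-Inf, sort(unique(c(case_scores, control_scores))))
  out <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(case_scores <= t), numeric(1L)),
    fpr = vapply(thr, function(t) mean(control_scores <= t), numeric(1L))
  )
  structure(out, class = c("roc_curve", "data.frame"))
}

check_roc_input <- function(case_scores, control_scores) {
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    stop_validation("both case and control score vectors must be nonempty")
  }
  if (anyNA(case_scores) || anyNA(control_scores)) {
    stop_validation("ROC scores must not contain missing values")
  }
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) estimator under the fixed orientation:
#' \code{P(case < control) + 0.5 P(case = control)} over all
#' case-control pairs. Identical to the trapezoidal area under
#' \code{\link{roc_curve}}.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(case_scores, control_scores) {
  check_roc_input(case_scores, control_scores)
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  # rank-sum of the controls counts pairs with control > case (+ half ties)
  (sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

#' Youden-optimal operating point
#'
#' Scans candidate cutoffs (midpoints between adjacent distinct pooled
#' scores, plus \code{-Inf}/\code{+Inf} sentinels) and returns the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward higher specificity, then toward the lower cutoff, making the
#' result deterministic.
#'
#' @inheritParams roc_curve
#' @param case_group,control_group Labels stored in the summary.
#' @return An object of class \code{roc_summary}: list with \code{auc},
#'   \code{cutoff}, \code{sensitivity}, \code{specificity}, \code{youden_j}
#'   and the group labels.
#' @export
optimal_binary_cutoff <- function(case_scores, control_scores,
                                  case_group = "case", control_group = "control") {
  check_roc_input(case_scores, control_scores)
  pooled <- sort(unique(c(case_scores, control_scores)))
  cand <- c(-Inf, if (length(pooled) > 1L)
    (pooled[-1L] + pooled[-length(pooled)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(case_scores <= t), numeric(1L))
  spec <- vapply(cand, function(t) mean(control_scores > t), numeric(1L))
  j <- sens + spec - 1
  best <- order(-j, -spec, cand)[1L]
  structure(
    list(auc = roc_auc(case_scores, control_scores),
         cutoff = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best],
         case_group = case_group, control_group = control_group),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: AUC %.3f; cutoff %.3g -> sensitivity %.0f%%, specificity %.0f%%\n",
    x$case_group, x$control_group, x$auc, x$cutoff,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' All pairwise ROC comparisons of a scored cohort
#'
#' Runs \code{\link{optimal_binary_cutoff}} on the normalized overall
#' score for the three severity-ordered comparisons (dementia vs NC, MCI
#' vs NC, dementia vs MCI), the more severe group as cases.
#'
#' @param scored A \code{\link{score_cohort}} result.
#' @param score Column holding the classifier score.
#' @return Named list of \code{roc_summary} objects.
#' @export
pairwise_roc <- function(scored, score = "overall_z") {
  x <- as.data.frame(scored)
  by_group <- split(x[[score]], factor(x$diagnosis, levels = DIAGNOSIS_LEVELS))
  pairs <- list(c("dementia", "NC"), c("MCI", "NC"), c("dementia", "MCI"))
  out <- lapply(pairs, function(p) {
    optimal_binary_cutoff(by_group[[p[1L]]], by_group[[p[2L]]],
                          case_group = p[1L], control_group = p[2L])
  })
  names(out) <- vapply(pairs, paste, character(1L), collapse = "_vs_")
  out
}
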