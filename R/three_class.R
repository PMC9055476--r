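# Three-class classification of NC / MCI / dementia from a single score.
#
# The score line is partitioned by a cutoff pair t- <= t+: dementia is
# predicted for score <= t-, MCI for t- < score <= t+, NC for score > t+
# (left-closed on the severe side). The volume under the three-class ROC
# surface (VUS) is the probability that a random (dementia, MCI, NC)
# triple is correctly ordered, with Mann-Whitney-style tie credits.

check_three_groups <- function(dem, mci, nc) {
  if (length(dem) == 0L || length(mci) == 0L || length(nc) == 0L) {
    stop_validation("all three score vectors must be nonempty")
  }
  if (anyNA(dem) || anyNA(mci) || anyNA(nc)) {
    stop_validation("three-class scores must not contain missing values")
  }
  invisible(NULL)
}

#' Volume under the three-class ROC surface
#'
#' Proportion over all (dementia, MCI, NC) score triples \code{(d, m, n)}
#' of correctly ordered \code{d < m < n}, with tie credits: 1 for a strict
#' ordering, 1/2 when exactly one of \code{d = m} or \code{m = n} holds
#' (the other relation strict), 1/6 for a triple tie, 0 otherwise. Equals
#' brute-force triple enumeration; 1/6 is the chance level when the three
#' groups share one continuous distribution, 1 indicates perfect
#' separation.
#'
#' @param dem_scores,mci_scores,nc_scores Score vectors per group (lower =
#'   more impaired).
#' @return VUS in \[0, 1\].
#' @export
vus_estimate <- function(dem_scores, mci_scores, nc_scores) {
  check_three_groups(dem_scores, mci_scores, nc_scores)
  d <- sort(dem_scores)
  n <- sort(nc_scores)
  total <- 0
  tie_fix <- 0
  for (m in mci_scores) {
    n_d_lt <- sum(d < m); n_d_eq <- sum(d == m)
    n_n_gt <- sum(n > m); n_n_eq <- sum(n == m)
    a <- n_d_lt + 0.5 * n_d_eq
    b <- n_n_gt + 0.5 * n_n_eq
    total <- total + a * b
    # a*b credits a triple tie 1/4; the convention says 1/6
    tie_fix <- tie_fix + n_d_eq * n_n_eq
  }
  (total - tie_fix / 12) /
    (length(dem_scores) * length(mci_scores) * length(nc_scores))
}

#' Per-group correct-classification rates for a cutoff pair
#'
#' Applies the decision rule (dementia: score \code{<= t_minus}; MCI:
#' \code{t_minus < score <= t_plus}; NC: \code{> t_plus}) and reports each
#' group's true positive rate, their sum (the generalized-Youden
#' objective), optionally a group-size-weighted overall accuracy, and the
#' VUS of the same scores.
#'
#' @param scores_by_group Named list with numeric elements \code{dementia},
#'   \code{MCI}, \code{NC}.
#' @param t_minus,t_plus Lower and upper cutoffs, \code{t_minus <= t_plus}.
#' @param weights \code{"sum"} for the unweighted sum of the three rates
#'   or \code{"weighted"} for group-size-weighted overall accuracy.
#' @return An object of class \code{three_class_result}.
#' @export
three_class_rates <- function(scores_by_group, t_minus, t_plus,
                              weights = c("sum", "weighted")) {
  weights <- match.arg(weights)
  g <- as_three_groups(scores_by_group)
  if (t_minus > t_plus) {
    stop_validation("t_minus (%g) must not exceed t_plus (%g)", t_minus, t_plus)
  }
  tpr <- c(
    dementia = mean(g$dementia <= t_minus),
    MCI = mean(g$MCI > t_minus & g$MCI <= t_plus),
    NC = mean(g$NC > t_plus)
  )
  n <- vapply(g, length, integer(1L))
  w <- if (weights == "sum") c(1, 1, 1) else unname(n[names(tpr)] / sum(n))
  structure(
    list(t_minus = t_minus, t_plus = t_plus, tpr = tpr,
         objective = sum(w * tpr), objective_kind = weights,
         vus = vus_estimate(g$dementia, g$MCI, g$NC), n = n),
    class = "three_class_result"
  )
}

as_three_groups <- function(scores_by_group) {
  need <- c("dementia", "MCI", "NC")
  if (!all(need %in% names(scores_by_group))) {
    stop_validation("scores_by_group must have elements: %s",
                    paste(need, collapse = ", "))
  }
  g <- lapply(scores_by_group[need], as.numeric)
  check_three_groups(g$dementia, g$MCI, g$NC)
  g
}

#' Optimal cutoff-pair search
#'
#' Exhaustive search over candidate cutoff pairs \code{(t-, t+)} with
#' \code{t- <= t+}, candidates being midpoints between adjacent distinct
#' pooled scores plus \code{-Inf}/\code{+Inf} sentinels — exact for
#' empirical distributions. Maximizes the sum of the three group-wise
#' true positive rates (generalized Youden; \code{objective = "weighted"}
#' instead maximizes group-size-weighted overall accuracy). Objective
#' ties are broken by the widest \code{t+ - t-} margin, then the smallest
#' \code{t-}, so the output is deterministic.
#'
#' @inheritParams three_class_rates
#' @param objective \code{"sum"} or \code{"weighted"}.
#' @return A \code{\link{three_class_rates}} result at the optimum.
#' @export
optimal_cutoff_pair <- function(scores_by_group, objective = c("sum", "weighted")) {
  objective <- match.arg(objective)
  g <- as_three_groups(scores_by_group)
  pooled <- sort(unique(c(g$dementia, g$MCI, g$NC)))
  cand <- c(-Inf, if (length(pooled) > 1L)
    (pooled[-1L] + pooled[-length(pooled)]) / 2, Inf)
  n <- vapply(g, length, integer(1L))
  w <- if (objective == "sum") c(dementia = 1, MCI = 1, NC = 1) else n / sum(n)
  Fd <- vapply(cand, function(t) mean(g$dementia <= t), numeric(1L))
  Fm <- vapply(cand, function(t) mean(g$MCI <= t), numeric(1L))
  Fn <- vapply(cand, function(t) mean(g$NC <= t), numeric(1L))
  # objective(c1, c2) = a(c1) + b(c2) + w_NC, separable in the two cutoffs
  a <- w[["dementia"]] * Fd - w[["MCI"]] * Fm
  b <- w[["MCI"]] * Fm - w[["NC"]] * Fn
  K <- length(cand)
  obj <- outer(a, b, `+`) + w[["NC"]]
  obj[lower.tri(obj)] <- -Inf  # enforce c1 <= c2
  best_val <- max(obj)
  hits <- which(obj >= best_val - 1e-12, arr.ind = TRUE)
  margin <- cand[hits[, 2L]] - cand[hits[, 1L]]
  margin[is.nan(margin)] <- 0  # both cutoffs at the same infinite sentinel
  pick <- order(-margin, cand[hits[, 1L]])[1L]
  three_class_rates(g, cand[hits[pick, 1L]], cand[hits[pick, 2L]],
                    weights = objective)
}

#' @export
print.three_class_result <- function(x, ...) {
  cat(sprintf("Three-class cutoffs: t- = %.3g, t+ = %.3g\n",
              x$t_minus, x$t_plus))
  cat(sprintf(
    "True positive rates: dementia %.0f%%, MCI %.0f%%, NC %.0f%% (%s objective %.3f)\n",
    100 * x$tpr[["dementia"]], 100 * x$tpr[["MCI"]], 100 * x$tpr[["NC"]],
    x$objective_kind, x$objective))
  cat(sprintf("VUS: %.3f\n", x$vus))
  invisible(x)
}

#' Three-class analysis of a scored cohort
#'
#' Splits the normalized overall score by diagnosis and runs
#' \code{\link{optimal_cutoff_pair}}.
#'
#' @param scored A \code{\link{score_cohort}} result.
#' @param score Column holding the classifier score.
#' @inheritParams optimal_cutoff_pair
#' @return A \code{three_class_result}.
#' @export
three_class_analysis <- function(scored, score = "overall_z",
                                 objective = c("sum", "weighted")) {
  x <- as.data.frame(scored)
  by_group <- split(x[[score]], factor(x$diagnosis, levels = DIAGNOSIS_LEVELS))
  optimal_cutoff_pair(list(dementia = by_group$dementia, MCI = by_group$MCI,
                           NC = by_group$NC), objective = match.arg(objective))
}
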