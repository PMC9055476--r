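#' Time-out penalty
#'
#' An assessment that timed out is scored as zero on its raw (native)
#' scale: the raw-score floor, denoting worst-case performance. The zero is
#' imposed before battery averaging and before normative standardization —
#' a z-score of zero would mean normative-average performance and could
#' not serve as a penalty. Input is not mutated.
#'
#' @param results Data frame of one participant's assessment results with
#'   columns \code{assessment, raw_score, timed_out} (see
#'   \code{\link{assessment_results}}).
#' @return The same data frame with timed-out raw scores set to 0.
#' @export
apply_timeout_penalty <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("assessment", "raw_score", "timed_out") %in% names(results)))
  results$raw_score[results$timed_out] <- 0
  results
}

#' Normative z-standardization
#'
#' Standardizes a raw score against the normative entry resolved for the
#' participant's age and device: \code{(raw - mean) / sd}. The result is on
#' a standard-normal scale where lower values indicate worse performance.
#'
#' @param raw Raw score on the assessment's native scale.
#' @param assessment Score name (one of the seven assessments or
#'   \code{"overall"}).
#' @param age Participant age in years.
#' @param device \code{"ipad"} or \code{"computer"}.
#' @param ref A \code{\link{normative_reference}}.
#' @return The z-standardized score.
#' @export
normalize_assessment <- function(raw, assessment, age, device, ref) {
  entry <- normative_lookup(ref, assessment, age, device)
  (raw - entry$mean) / entry$sd
}

#' Battery overall raw score
#'
#' Arithmetic mean of the raw assessment scores after the time-out penalty:
#' completed assessments contribute their score, timed-out assessments
#' contribute zero. Assessments that are missing without having timed out
#' are excluded from the mean (and reported via a warning by
#' \code{\link{score_cohort}}).
#'
#' @param results Penalized assessment results
#'   (\code{\link{apply_timeout_penalty}} already applied).
#' @return The battery average on the raw scale.
#' @export
battery_overall <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop_validation("battery_overall: no results")
  x <- results$raw_score
  if (all(is.na(x))) stop_validation("battery_overall: all raw scores missing")
  mean(x, na.rm = TRUE)
}

#' Score a cohort against a normative reference
#'
#' Applies, per participant: the time-out penalty, per-assessment normative
#' z-standardization, the battery average of penalized raw scores, and
#' z-standardization of that average against the \code{"overall"} normative
#' entry. Deterministic: a pure function of \code{(cohort, ref)}.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param ref A \code{\link{normative_reference}}.
#' @return A \code{scored_cohort} data frame with one row per participant:
#'   \code{id, diagnosis}, demographics carried over for modeling
#'   (\code{age, sex, education, administration, device,
#'   battery_duration_min}), the seven \code{<name>_z} columns,
#'   \code{overall_raw}, \code{overall_z} and \code{n_timeouts}.
#' @export
score_cohort <- function(cohort, ref) {
  stopifnot(inherits(cohort, "cohort"), inherits(ref, "normative_ref"))
  n <- nrow(cohort)
  zmat <- matrix(NA_real_, n, length(ASSESSMENTS),
                 dimnames = list(NULL, paste0(ASSESSMENTS, "_z")))
  overall_raw <- numeric(n)
  overall_z <- numeric(n)
  n_timeouts <- integer(n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    res <- assessment_results(cohort, cohort$id[i])
    res <- apply_timeout_penalty(res)
    skipped <- is.na(res$raw_score)
    n_skipped <- n_skipped + sum(skipped)
    for (j in seq_along(ASSESSMENTS)) {
      if (!skipped[j]) {
        zmat[i, j] <- normalize_assessment(res$raw_score[j], ASSESSMENTS[j],
                                           cohort$age[i], cohort$device[i], ref)
      }
    }
    overall_raw[i] <- battery_overall(res)
    overall_z[i] <- normalize_assessment(overall_raw[i], "overall",
                                         cohort$age[i], cohort$device[i], ref)
    n_timeouts[i] <- sum(res$timed_out)
  }
  if (n_skipped > 0L) {
    warning(sprintf(
      "%d assessment(s) missing without time-out; excluded from battery averages",
      n_skipped))
  }
  out <- data.frame(
    id = cohort$id,
    diagnosis = cohort$diagnosis,
    age = cohort$age,
    sex = cohort$sex,
    education = cohort$education,
    administration = cohort$administration,
    device = cohort$device,
    battery_duration_min = cohort$battery_duration_min,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(zmat))
  out$overall_raw <- overall_raw
  out$overall_z <- overall_z
  out$n_timeouts <- n_timeouts
  structure(out, class = c("scored_cohort", "data.frame"),
            reference_id = attr(ref, "reference_id") %||% "normative_ref")
}

#' @export
print.scored_cohort <- function(x, ...) {
  g <- factor(x$diagnosis, levels = DIAGNOSIS_LEVELS)
  m <- tapply(x$overall_z, g, mean)
  cat(sprintf(
    "Scored cohort: %d participants; mean overall z: NC %.2f, MCI %.2f, dementia %.2f\n",
    nrow(x), m[["NC"]], m[["MCI"]], m[["dementia"]]))
  invisible(x)
}
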