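#' Participant cohorts
#'
#' A cohort is one row per participant: demographics, diagnosis group, the
#' battery duration in minutes, and for each of the seven assessments a raw
#' score, a time-out flag, and an assessment duration in seconds. A raw
#' score is present whenever the assessment was completed
#' (\code{timed_out = FALSE}); a timed-out assessment records no raw score
#' (the scoring stage supplies the zero-score penalty).
#'
#' Column schema (also the CSV schema): \code{id, age, sex, education,
#' administration, device, diagnosis, battery_duration_min}, then per
#' assessment \code{<name>_raw}, \code{<name>_timed_out},
#' \code{<name>_duration_s}.
#'
#' @param df Data frame following the schema above.
#' @param provenance Optional free-text provenance (seed, config hash, path).
#' @return An object of class \code{cohort} (a validated data frame).
#' @export
cohort <- function(df, provenance = NULL) {
  df <- as.data.frame(df)
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop_schema("cohort is missing required column(s): %s",
                paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_validation("cohort must contain at least one record")
  df <- df[cohort_columns()]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop_validation("duplicate participant id '%s'", df$id[duplicated(df$id)][1L])
  }
  check_level(df$diagnosis, DIAGNOSIS_LEVELS, "diagnosis", where = "row")
  check_level(df$sex, SEX_LEVELS, "sex", where = "row")
  check_level(df$education, EDUCATION_LEVELS, "education", where = "row")
  check_level(df$administration, ADMIN_LEVELS, "administration", where = "row")
  check_level(df$device, DEVICE_LEVELS, "device", where = "row")
  if (any(!is.finite(df$age) | df$age <= 0)) {
    stop_validation("age must be a positive number (row %d)",
                    which(!is.finite(df$age) | df$age <= 0)[1L])
  }
  if (any(!is.finite(df$battery_duration_min) | df$battery_duration_min <= 0)) {
    stop_validation("battery_duration_min must be positive (row %d)",
                    which(!is.finite(df$battery_duration_min) |
                            df$battery_duration_min <= 0)[1L])
  }
  for (a in ASSESSMENTS) {
    to <- df[[paste0(a, "_timed_out")]]
    if (!is.logical(to) || anyNA(to)) {
      stop_validation("%s_timed_out must be TRUE/FALSE with no missing values", a)
    }
    # missing-but-not-timed-out raw scores are allowed (skipped assessment);
    # they are excluded from the battery average at scoring time, with a
    # warning there rather than here.
    dur <- df[[paste0(a, "_duration_s")]]
    if (any(!is.na(dur) & dur < 0)) {
      stop_validation("%s_duration_s must be nonnegative", a)
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("cohort", "data.frame"),
            provenance = provenance)
}

cohort_columns <- function() {
  c("id", "age", "sex", "education", "administration", "device",
    "diagnosis", "battery_duration_min",
    as.vector(t(outer(ASSESSMENTS, c("_raw", "_timed_out", "_duration_s"),
                      paste0))))
}

#' @export
print.cohort <- function(x, ...) {
  counts <- table(factor(x$diagnosis, levels = DIAGNOSIS_LEVELS))
  cat(sprintf("Cohort: %d participants (NC %d, MCI %d, dementia %d)\n",
              nrow(x), counts[["NC"]], counts[["MCI"]], counts[["dementia"]]))
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("Provenance:", prov, "\n")
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  g <- factor(object$diagnosis, levels = DIAGNOSIS_LEVELS)
  out <- data.frame(
    group = DIAGNOSIS_LEVELS,
    n = as.vector(table(g)),
    age_mean = as.vector(tapply(object$age, g, mean)),
    age_sd = as.vector(tapply(object$age, g, stats::sd)),
    pct_female = as.vector(tapply(object$sex == "female", g, mean)) * 100,
    duration_median_min = as.vector(tapply(object$battery_duration_min, g,
                                           stats::median))
  )
  out
}

#' Extract one participant's assessment results
#'
#' Long-form view of a single cohort row: one row per assessment with
#' columns \code{assessment, raw_score, timed_out, duration_s}. This is the
#' shape the scoring primitives (\code{\link{apply_timeout_penalty}},
#' \code{\link{battery_overall}}) operate on.
#'
#' @param cohort A \code{\link{cohort}}.
#' @param id Participant id.
#' @return Data frame with 7 rows.
#' @export
assessment_results <- function(cohort, id) {
  stopifnot(inherits(cohort, "cohort"))
  i <- match(id, cohort$id)
  if (is.na(i)) stop_validation("no participant with id '%s'", id)
  data.frame(
    assessment = ASSESSMENTS,
    raw_score = vapply(ASSESSMENTS, function(a) cohort[[paste0(a, "_raw")]][i],
                       numeric(1L)),
    timed_out = vapply(ASSESSMENTS, function(a)
      cohort[[paste0(a, "_timed_out")]][i], logical(1L)),
    duration_s = vapply(ASSESSMENTS, function(a)
      cohort[[paste0(a, "_duration_s")]][i], numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read / write a cohort CSV
#'
#' Comma-separated, UTF-8, \code{.} decimal, header row required; booleans
#' serialized as \code{true}/\code{false}; missing raw scores as empty
#' fields (the education level \code{"NA"} is a literal label, not a
#' missing value). \code{write_cohort_csv} serializes numbers at full
#' precision so that read-write round-trips are value-identical.
#'
#' @param path File path.
#' @return \code{read_cohort_csv}: a \code{\link{cohort}};
#'   \code{write_cohort_csv}: \code{path}, invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  missing <- setdiff(cohort_columns(), names(df))
  if (length(missing)) {
    stop_schema("cohort CSV %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  num_cols <- c("age", "battery_duration_min",
                paste0(ASSESSMENTS, "_raw"), paste0(ASSESSMENTS, "_duration_s"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in paste0(ASSESSMENTS, "_timed_out")) {
    v <- tolower(df[[col]])
    if (any(!v %in% c("true", "false"))) {
      stop_validation("column %s must be true/false", col)
    }
    df[[col]] <- v == "true"
  }
  cohort(df, provenance = path)
}

#' @param cohort A \code{\link{cohort}}.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- cogdx::cohort(cohort)  # revalidate
  out <- as.data.frame(cohort)
  num_cols <- c("age", "battery_duration_min",
                paste0(ASSESSMENTS, "_raw"), paste0(ASSESSMENTS, "_duration_s"))
  for (col in num_cols) out[[col]] <- format_num(out[[col]])
  for (col in paste0(ASSESSMENTS, "_timed_out")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_cogdx("cannot open '%s' for writing: %s", path, conditionMessage(e),
               class = "cogdx_io_error"))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
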