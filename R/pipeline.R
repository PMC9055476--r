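#' Time-out rate table
#'
#' Fraction of participants per diagnosis group whose timed assessments
#' (Stroop, Trails A/B) timed out.
#'
#' @param cohort A \code{\link{cohort}}.
#' @return Data frame: one row per timed assessment, one column per group.
#' @export
timeout_rate_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  g <- factor(cohort$diagnosis, levels = DIAGNOSIS_LEVELS)
  out <- data.frame(assessment = TIMED_ASSESSMENTS, stringsAsFactors = FALSE)
  for (lev in DIAGNOSIS_LEVELS) {
    out[[lev]] <- vapply(TIMED_ASSESSMENTS, function(a) {
      flags <- cohort[[paste0(a, "_timed_out")]][g == lev]
      if (length(flags) == 0L) NA_real_ else mean(flags)
    }, numeric(1L))
  }
  out
}

#' Run the full validation pipeline
#'
#' Orchestrates generate (or load) -> score -> demographics -> adjusted
#' group comparisons -> time-out rates -> duration comparison -> binary
#' ROC -> three-class classification, and optionally writes every table
#' to an output directory (CSV for tables, JSON for scalar summaries).
#' Deterministic given the configuration, including its seed.
#'
#' @param config Either a \code{\link{generator_config}} (synthetic mode)
#'   or a list \code{list(cohort_csv =, normative_csv =)} (file mode).
#' @param out_dir Optional output directory; created if missing.
#' @param iqr_filter Apply IQR outlier filtering to the per-assessment
#'   score comparisons (never to overall-score, duration or ROC analyses)?
#' @param objective Three-class objective, \code{"sum"} or
#'   \code{"weighted"}.
#' @return An object of class \code{report_bundle}: list with elements
#'   \code{cohort, scored, demographics, assessment_comparisons,
#'   overall_comparison, duration_comparison, timeout_rates, roc,
#'   three_class, provenance}.
#' @export
run_pipeline <- function(config, out_dir = NULL, iqr_filter = TRUE,
                         objective = c("sum", "weighted")) {
  objective <- match.arg(objective)
  stage <- "input"
  result <- tryCatch({
    if (inherits(config, "generator_config")) {
      cohort <- generate_cohort(config)
      ref <- config$reference
      prov <- sprintf("synthetic(seed=%d)", config$seed)
    } else if (is.list(config) &&
               all(c("cohort_csv", "normative_csv") %in% names(config))) {
      cohort <- read_cohort_csv(config$cohort_csv)
      ref <- read_normative_reference(config$normative_csv)
      prov <- sprintf("files(%s, %s)", config$cohort_csv, config$normative_csv)
    } else {
      stop_validation(
        "config must be a generator_config or list(cohort_csv=, normative_csv=)")
    }

    stage <- "score"
    scored <- score_cohort(cohort, ref)

    stage <- "demographics"
    demo <- demographics_table(cohort)

    stage <- "compare"
    assessment_cmp <- lapply(ASSESSMENTS, function(a) {
      compare_groups(scored, paste0(a, "_z"), iqr = iqr_filter)
    })
    names(assessment_cmp) <- ASSESSMENTS
    overall_cmp <- compare_groups(scored, "overall_z", iqr = FALSE)
    duration_cmp <- compare_durations(cohort)
    to_rates <- timeout_rate_table(cohort)

    stage <- "roc"
    roc <- pairwise_roc(scored)

    stage <- "three-class"
    tc <- three_class_analysis(scored, objective = objective)

    structure(
      list(cohort = cohort, scored = scored, demographics = demo,
           assessment_comparisons = assessment_cmp,
           overall_comparison = overall_cmp,
           duration_comparison = duration_cmp,
           timeout_rates = to_rates, roc = roc, three_class = tc,
           provenance = list(input = prov, iqr_filter = iqr_filter,
                             objective = objective,
                             package_version = as.character(
                               utils::packageVersion("cogdx")))),
      class = "report_bundle"
    )
  }, cogdx_error = function(e) {
    stop_cogdx("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
               class = "cogdx_pipeline_error")
  })

  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

contrast_row <- function(cmp, outcome) {
  e <- cmp$emm
  ct <- cmp$contrasts
  data.frame(
    outcome = outcome,
    emm_NC = e$emm[e$group == "NC"], se_NC = e$se[e$group == "NC"],
    emm_MCI = e$emm[e$group == "MCI"], se_MCI = e$se[e$group == "MCI"],
    emm_dementia = e$emm[e$group == "dementia"],
    se_dementia = e$se[e$group == "dementia"],
    est_dem_vs_NC = ct$estimate[1L], p_dem_vs_NC = ct$p_adjusted[1L],
    est_dem_vs_MCI = ct$estimate[2L], p_dem_vs_MCI = ct$p_adjusted[2L],
    est_MCI_vs_NC = ct$estimate[3L], p_MCI_vs_NC = ct$p_adjusted[3L],
    n_removed = cmp$n_removed,
    stringsAsFactors = FALSE
  )
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(bundle$cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(as.data.frame(bundle$scored),
                   file.path(out_dir, "scored.csv"), row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(bundle$demographics),
                   file.path(out_dir, "demographics.csv"), row.names = FALSE)
  cmp_rows <- do.call(rbind, c(
    lapply(names(bundle$assessment_comparisons), function(a) {
      contrast_row(bundle$assessment_comparisons[[a]], a)
    }),
    list(contrast_row(bundle$overall_comparison, "overall"),
         contrast_row(bundle$duration_comparison, "battery_duration_min"))
  ))
  utils::write.csv(cmp_rows, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$timeout_rates,
                   file.path(out_dir, "timeout_rates.csv"), row.names = FALSE)
  roc_list <- lapply(bundle$roc, function(r) {
    r[c("auc", "cutoff", "sensitivity", "specificity", "case_group",
        "control_group")]
  })
  jsonlite::write_json(roc_list, file.path(out_dir, "roc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  tc <- bundle$three_class
  jsonlite::write_json(
    list(t_minus = tc$t_minus, t_plus = tc$t_plus,
         tpr_nc = tc$tpr[["NC"]], tpr_mci = tc$tpr[["MCI"]],
         tpr_dementia = tc$tpr[["dementia"]],
         objective = tc$objective, objective_kind = tc$objective_kind,
         vus = tc$vus),
    file.path(out_dir, "three_class.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  print(x$cohort)
  cat("\nDemographics tests:\n")
  print(x$demographics)
  cat("\nOverall score comparison:\n")
  print(x$overall_comparison)
  cat("\nBinary ROC (overall score):\n")
  for (r in x$roc) print(r)
  cat("\nThree-class classification:\n")
  print(x$three_class)
  invisible(x)
}
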