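#' IQR outlier filter
#'
#' Keeps values inside the Tukey fences
#' \code{[Q1 - 1.5 IQR, Q3 + 1.5 IQR]}, with quartiles computed by linear
#' interpolation between order statistics (\code{\link[stats]{quantile}}
#' type 7). Order of the surviving values is preserved. Applied per
#' assessment to normalized scores before the covariate-adjusted
#' comparison; the overall-score and ROC analyses are never filtered.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return \code{iqr_filter}: the surviving values; \code{iqr_keep}: a
#'   logical mask over \code{values}.
#' @examples
#' iqr_filter(c(0, 0, 0, 0, 10))  # IQR 0, fences [0, 0] -> drops the 10
#' @export
iqr_filter <- function(values) {
  values[iqr_keep(values)]
}

#' @rdname iqr_filter
#' @export
iqr_keep <- function(values) {
  if (length(values) < 4L || anyNA(values)) {
    stop_validation("iqr_filter needs at least 4 non-missing values")
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values >= q[1L] - 1.5 * iqr & values <= q[2L] + 1.5 * iqr
}

#' Covariate-adjusted outcome model
#'
#' Ordinary least squares of an outcome on diagnosis group (3-level
#' factor) plus age (linear), sex and administration type — the adjustment
#' set used for every score and duration comparison.
#'
#' @param data Data frame containing \code{diagnosis, age, sex,
#'   administration} and the outcome column (a \code{\link{score_cohort}}
#'   result, or a \code{\link{cohort}} for duration outcomes).
#' @param outcome Name of the outcome column.
#' @return An object of class \code{adjusted_fit}: the underlying
#'   \code{lm} fit plus the modeling frame, with \code{coef},
#'   \code{print} and \code{summary} methods.
#' @export
fit_adjusted_model <- function(data, outcome) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    stop_schema("outcome column '%s' not found", outcome)
  }
  frame <- data.frame(
    .y = data[[outcome]],
    diagnosis = factor(data$diagnosis, levels = DIAGNOSIS_LEVELS),
    age = data$age,
    sex = factor(data$sex, levels = SEX_LEVELS),
    administration = factor(data$administration, levels = ADMIN_LEVELS)
  )
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  frame$diagnosis <- droplevels(frame$diagnosis)
  n_groups <- nlevels(frame$diagnosis)
  if (n_groups < 2L) {
    stop_validation("need at least 2 nonempty diagnosis groups, got %d", n_groups)
  }
  frame$sex <- droplevels(frame$sex)
  frame$administration <- droplevels(frame$administration)
  rhs <- c("diagnosis", "age",
           if (nlevels(frame$sex) > 1L) "sex",
           if (nlevels(frame$administration) > 1L) "administration")
  fml <- stats::reformulate(rhs, response = ".y")
  fit <- stats::lm(fml, data = frame)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_validation("design matrix is rank deficient; aliased term(s): %s",
                    paste(aliased, collapse = ", "))
  }
  structure(
    list(outcome_name = outcome, lm = fit, frame = frame,
         residual_df = fit$df.residual, n_groups = n_groups),
    class = "adjusted_fit"
  )
}

#' @export
coef.adjusted_fit <- function(object, ...) stats::coef(object$lm)

#' @export
print.adjusted_fit <- function(x, ...) {
  cat(sprintf("Adjusted linear model for '%s' (n = %d, residual df = %d)\n",
              x$outcome_name, nrow(x$frame), x$residual_df))
  print(stats::coef(x$lm))
  invisible(x)
}

#' @export
summary.adjusted_fit <- function(object, ...) summary(object$lm)

#' Estimated marginal means per diagnosis group
#'
#' Model predictions per diagnosis group at age fixed at its sample mean,
#' averaging with equal weights over the levels of sex and administration
#' type; standard errors follow from the coefficient covariance.
#'
#' @param fit An \code{\link{fit_adjusted_model}} result.
#' @return A data frame of class \code{emm_table} with columns
#'   \code{group, emm, se, df}; the underlying \code{emmGrid} is attached
#'   as attribute \code{"grid"} for downstream contrasts.
#' @export
estimated_marginal_means <- function(fit) {
  stopifnot(inherits(fit, "adjusted_fit"))
  grid <- emmeans::emmeans(fit$lm, "diagnosis", data = fit$frame)
  s <- as.data.frame(summary(grid))
  out <- data.frame(group = as.character(s$diagnosis),
                    emm = s$emmean, se = s$SE, df = s$df,
                    stringsAsFactors = FALSE)
  structure(out, class = c("emm_table", "data.frame"), grid = grid)
}

#' Tukey-adjusted pairwise contrasts
#'
#' All three pairwise differences of estimated marginal means, oriented
#' more-severe minus less-severe (dementia vs NC, dementia vs MCI, MCI vs
#' NC), with p-values from the studentized-range distribution (3 means,
#' the fit's residual df). Adjustment is applied within the outcome's
#' three contrasts only.
#'
#' @param fit An \code{\link{fit_adjusted_model}} result with all three
#'   groups present.
#' @param emm Optionally, the \code{\link{estimated_marginal_means}} table
#'   for \code{fit} (recomputed when omitted).
#' @return A data frame of class \code{contrast_table} with columns
#'   \code{contrast, estimate, se, df, t_ratio, p_adjusted}.
#' @export
tukey_contrasts <- function(fit, emm = NULL) {
  stopifnot(inherits(fit, "adjusted_fit"))
  if (fit$n_groups < 3L) {
    stop_validation("tukey_contrasts requires all three diagnosis groups; got %d",
                    fit$n_groups)
  }
  if (is.null(emm)) emm <- estimated_marginal_means(fit)
  grid <- attr(emm, "grid")
  if (is.null(grid)) grid <- emmeans::emmeans(fit$lm, "diagnosis", data = fit$frame)
  prs <- summary(emmeans::contrast(grid, method = "revpairwise",
                                   adjust = "tukey"))
  prs <- as.data.frame(prs)
  lab <- gsub(" - ", " vs ", prs$contrast)
  out <- data.frame(contrast = lab, estimate = prs$estimate, se = prs$SE,
                    df = prs$df, t_ratio = prs$t.ratio,
                    p_adjusted = prs$p.value, stringsAsFactors = FALSE)
  want <- c("dementia vs NC", "dementia vs MCI", "MCI vs NC")
  out <- out[match(want, out$contrast), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contrast_table", "data.frame"))
}

#' @export
print.contrast_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$estimate <- sprintf("%.2f", y$estimate)
  y$se <- sprintf("%.2f", y$se)
  y$p_adjusted <- format.pval(y$p_adjusted, digits = 2, eps = 1e-3)
  print(y[c("contrast", "estimate", "se", "p_adjusted")], row.names = FALSE)
  invisible(x)
}

#' Contrast arithmetic from group means
#'
#' Pairwise more-severe-minus-less-severe differences of per-group means:
#' the arithmetic connecting a table of estimated marginal means to its
#' contrast-estimate column.
#'
#' @param emms Named numeric vector with elements \code{NC}, \code{MCI},
#'   \code{dementia}.
#' @return Named vector of the three contrast estimates.
#' @examples
#' pairwise_contrast_estimates(c(NC = 0.71, MCI = -2.15, dementia = -5.63))
#' @export
pairwise_contrast_estimates <- function(emms) {
  stopifnot(all(DIAGNOSIS_LEVELS %in% names(emms)))
  c("dementia vs NC" = unname(emms["dementia"] - emms["NC"]),
    "dementia vs MCI" = unname(emms["dementia"] - emms["MCI"]),
    "MCI vs NC" = unname(emms["MCI"] - emms["NC"]))
}

#' One-call adjusted group comparison
#'
#' Fits the covariate-adjusted model for one outcome, optionally after IQR
#' outlier filtering of the outcome, and returns estimated marginal means
#' with Tukey-adjusted pairwise contrasts.
#'
#' @param data A \code{\link{score_cohort}} result (or any data frame with
#'   the covariates and outcome).
#' @param outcome Outcome column name, e.g. \code{"overall_z"} or
#'   \code{"flanker_z"} or \code{"battery_duration_min"}.
#' @param iqr Apply the IQR filter to the outcome before fitting?
#' @return An object of class \code{group_comparison}: list with the
#'   \code{fit}, \code{emm} table, \code{contrasts} table and the number
#'   of observations removed by filtering.
#' @export
compare_groups <- function(data, outcome, iqr = FALSE) {
  data <- as.data.frame(data)
  n_removed <- 0L
  if (iqr) {
    keep <- iqr_keep(data[[outcome]])
    n_removed <- sum(!keep)
    data <- data[keep, , drop = FALSE]
  }
  fit <- fit_adjusted_model(data, outcome)
  emm <- estimated_marginal_means(fit)
  contrasts <- tukey_contrasts(fit, emm)
  structure(list(outcome = outcome, fit = fit, emm = emm,
                 contrasts = contrasts, n_removed = n_removed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison for '%s'", x$outcome))
  if (x$n_removed > 0L) cat(sprintf(" (IQR filter removed %d)", x$n_removed))
  cat("\nEstimated marginal means:\n")
  e <- x$emm
  cat(paste(sprintf("  %s %.2f (%.2f)", e$group, e$emm, e$se), collapse = "\n"),
      "\n")
  print(x$contrasts)
  invisible(x)
}

#' Battery-duration comparison
#'
#' The same adjusted-model / EMM / Tukey machinery with the battery
#' duration in minutes as the outcome.
#'
#' @param cohort A \code{\link{cohort}} (or scored cohort).
#' @return A \code{\link{compare_groups}} result.
#' @export
compare_durations <- function(cohort) {
  compare_groups(as.data.frame(cohort), "battery_duration_min", iqr = FALSE)
}

#' Demographics comparison table
#'
#' Group comparison of the demographic margins: age by one-way ANOVA
#' across the three groups; sex, education (with \code{"NA"} as its own
#' level) and administration type by Pearson chi-square on the full
#' contingency table.
#'
#' @param cohort A \code{\link{cohort}}.
#' @return A data frame of class \code{demographics_table} with one row
#'   per variable: \code{variable, test, statistic, df, p_value}. Group
#'   count/percentage summaries are attached as attribute
#'   \code{"group_summaries"}.
#' @export
demographics_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  g <- factor(cohort$diagnosis, levels = DIAGNOSIS_LEVELS)
  if (any(table(g) == 0L)) {
    stop_validation("demographics_table requires all three groups nonempty")
  }
  age_fit <- stats::anova(stats::lm(cohort$age ~ g))
  rows <- list(data.frame(variable = "age", test = "anova",
                          statistic = age_fit[["F value"]][1L],
                          df = age_fit[["Df"]][1L],
                          p_value = age_fit[["Pr(>F)"]][1L]))
  summaries <- list()
  cat_vars <- c("sex", "education", "administration")
  for (v in cat_vars) {
    tab <- table(factor(cohort[[v]]), g)
    if (nrow(tab) < 2L) {
      # a single observed level carries no contrast to test
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = "chi-square",
        statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    } else {
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = "chi-square",
        statistic = unname(chi$statistic), df = unname(chi$parameter),
        p_value = chi$p.value)
    }
    summaries[[v]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("demographics_table", "data.frame"),
            group_summaries = summaries)
}

#' @export
print.demographics_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$statistic <- sprintf("%.2f", y$statistic)
  y$p_value <- format.pval(y$p_value, digits = 2, eps = 1e-3)
  print(y, row.names = FALSE)
  invisible(x)
}
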