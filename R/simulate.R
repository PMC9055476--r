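#' Generator configuration
#'
#' Bundles every knob of the synthetic-cohort simulator. The simulator
#' draws, per participant: demographics from group-specific margins; a
#' shared ability factor plus per-assessment residuals (intraclass
#' correlation \code{icc}) on the normative z scale; a contaminated-normal
#' heavy left tail for the dementia group; time-outs for the Stroop and
#' Trail Making A/B assessments, taken as the lowest-quantile latent
#' residuals at the configured group rate (time-outs arise from response
#' delays, so they hit the worst latent performances); and log-normal
#' battery durations. Raw scores are \code{reference mean + reference sd *
#' (effect + noise)}, floored at zero; a timed-out assessment records no
#' raw score (the scoring stage supplies the zero penalty).
#'
#' @param group_sizes Named integer vector \code{c(NC=, MCI=, dementia=)}.
#' @param age_mean_sd 3x2 matrix (rows NC/MCI/dementia): mean and SD of age
#'   in years.
#' @param sex_p_female,administration_p_remote Named per-group fractions.
#' @param device_p_computer Single fraction: probability a participant uses
#'   a touchscreen computer rather than an iPad.
#' @param education_p 4x3 matrix of education-level probabilities
#'   (rows: the four education levels, columns: groups).
#' @param assessment_effects 7x3 matrix (assessments x groups) of mean
#'   shifts in normative-SD units.
#' @param residual_sd Length-7 positive vector of individual-level SDs in
#'   normative-SD units.
#' @param icc Fraction of residual variance shared across assessments
#'   within a participant (general-ability factor).
#' @param dementia_tail \code{c(fraction, shift, inflation)}: a fraction of
#'   dementia participants get an extra mean shift (z units) and an
#'   SD-inflation factor — a contaminated normal producing the heavy left
#'   tail seen in impaired samples.
#' @param timeout_base_p Named per-group time-out probability, applied to
#'   each of the three timed assessments.
#' @param duration_model 3x2 matrix (rows groups): median battery duration
#'   in minutes and log-scale SD of a log-normal.
#' @param reference A \code{\link{normative_reference}} used both to map z
#'   shifts onto raw scales at generation time and to score the cohort.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A \code{generator_config} list.
#' @seealso \code{\link{calibrated_defaults}} for the study-calibrated
#'   parameterization, \code{\link{generate_cohort}}.
#' @export
generator_config <- function(group_sizes,
                             age_mean_sd,
                             sex_p_female,
                             administration_p_remote,
                             device_p_computer,
                             education_p,
                             assessment_effects,
                             residual_sd,
                             icc,
                             dementia_tail,
                             timeout_base_p,
                             duration_model,
                             reference,
                             seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes,
    age_mean_sd = age_mean_sd,
    sex_p_female = sex_p_female,
    administration_p_remote = administration_p_remote,
    device_p_computer = device_p_computer,
    education_p = education_p,
    assessment_effects = assessment_effects,
    residual_sd = residual_sd,
    icc = icc,
    dementia_tail = dementia_tail,
    timeout_base_p = timeout_base_p,
    duration_model = duration_model,
    reference = reference,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg$reference, "normative_ref"))
  chk_frac <- function(x, what) {
    if (any(!is.finite(x) | x < 0 | x > 1)) {
      stop_validation("%s must be fractions in [0, 1]", what)
    }
  }
  if (!all(DIAGNOSIS_LEVELS %in% names(cfg$group_sizes))) {
    stop_validation("group_sizes must be named NC, MCI, dementia")
  }
  if (any(cfg$group_sizes < 0)) stop_validation("group_sizes must be >= 0")
  chk_frac(cfg$sex_p_female, "sex_p_female")
  chk_frac(cfg$administration_p_remote, "administration_p_remote")
  chk_frac(cfg$device_p_computer, "device_p_computer")
  chk_frac(cfg$education_p, "education_p")
  chk_frac(cfg$timeout_base_p, "timeout_base_p")
  chk_frac(cfg$icc, "icc")
  chk_frac(cfg$dementia_tail[1L], "dementia_tail fraction")
  if (cfg$dementia_tail[3L] <= 0) stop_validation("tail inflation must be > 0")
  if (any(cfg$residual_sd <= 0)) stop_validation("residual_sd must be > 0")
  stopifnot(nrow(cfg$assessment_effects) == length(ASSESSMENTS),
            ncol(cfg$assessment_effects) == 3L,
            length(cfg$residual_sd) == length(ASSESSMENTS))
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort generator: n = %d/%d/%d (NC/MCI/dementia), seed %d\n",
    x$group_sizes[["NC"]], x$group_sizes[["MCI"]],
    x$group_sizes[["dementia"]], x$seed))
  if (!is.null(attr(x, "calibration"))) {
    cal <- attr(x, "calibration")
    cat(sprintf(
      "Calibrated: weight %.4f/assessment, penalty depth %.2f normative SDs\n",
      cal$w, cal$r))
  }
  invisible(x)
}

# Study-reported constants the calibrated generator is built from:
# group sizes, demographic margins, per-assessment and overall estimated
# marginal means with their SEs, battery-duration medians and IQRs.
study_constants <- function() {
  groups <- DIAGNOSIS_LEVELS
  effects <- matrix(c(
    # NC      MCI     dementia
    0.17, -1.93, -3.36,   # immediate_recognition
    0.06, -2.16, -2.92,   # delayed_recognition
    0.80, -0.21, -1.23,   # digit_symbol
    0.76, -0.74, -2.64,   # flanker
    -0.43, -0.63, -0.91,  # stroop
    -0.01, -0.75, -1.69,  # trails_a
    0.51,  0.21, -0.16    # trails_b
  ), ncol = 3L, byrow = TRUE, dimnames = list(ASSESSMENTS, groups))
  se <- matrix(c(
    0.44, 0.50, 0.36,
    0.34, 0.39, 0.28,
    0.27, 0.29, 0.29,
    0.45, 0.51, 0.41,
    0.12, 0.13, 0.12,
    0.33, 0.36, 0.30,
    0.21, 0.23, 0.24
  ), ncol = 3L, byrow = TRUE, dimnames = list(ASSESSMENTS, groups))
  list(
    group_sizes = c(NC = 35L, MCI = 22L, dementia = 42L),
    age_mean_sd = matrix(c(67.8, 9.6, 73.5, 5.9, 71.5, 9.0), ncol = 2L,
                         byrow = TRUE,
                         dimnames = list(groups, c("mean", "sd"))),
    sex_p_female = c(NC = 25 / 35, MCI = 8 / 22, dementia = 16 / 42),
    administration_p_remote = c(NC = 6 / 35, MCI = 6 / 22, dementia = 13 / 42),
    education_p = matrix(c(
      2 / 35, 2 / 22, 8 / 42,
      10 / 35, 6 / 22, 11 / 42,
      14 / 35, 9 / 22, 16 / 42,
      9 / 35, 5 / 22, 7 / 42
    ), ncol = 3L, byrow = TRUE,
    dimnames = list(EDUCATION_LEVELS, groups)),
    assessment_effects = effects,
    assessment_se = se,
    overall_emm = c(NC = 0.71, MCI = -2.15, dementia = -5.63),
    overall_se = c(NC = 0.55, MCI = 0.62, dementia = 0.45),
    duration_median = c(NC = 17.8, MCI = 21.5, dementia = 30.5),
    duration_iqr = matrix(c(15.4, 19.6, 19.3, 24.2, 23.4, 37.1), ncol = 2L,
                          byrow = TRUE,
                          dimnames = list(groups, c("q1", "q3")))
  )
}

# Expected sum over assessments of E[z_i | group], given effects etil
# (7 x 3, tail shift folded into the dementia column), residual sds, the
# timed-assessment set, group time-out rates p, and the dementia
# contamination's SD-inflation mixture factor. Time-outs censor the lowest
# p-quantile of the latent residual, so the retained mean gains
# sd * dnorm(qnorm(p)); the penalty value itself (-m/s) enters separately.
calibration_design <- function(etil, sigma, p, mix_factor) {
  timed <- ASSESSMENTS %in% TIMED_ASSESSMENTS
  vapply(seq_len(3L), function(g) {
    sum(etil[, g]) - p[g] * sum(etil[timed, g]) +
      stats::dnorm(stats::qnorm(p[g])) * mix_factor[g] * sum(sigma[timed])
  }, numeric(1L))
}

#' Study-calibrated generator defaults
#'
#' Returns a \code{\link{generator_config}} whose group sizes (35/22/42),
#' age, sex, education and administration margins match the study sample,
#' whose per-assessment mean shifts are the reported estimated marginal
#' means, and whose individual-level SDs are reconstructed as
#' \code{SE * sqrt(n)} (averaged over groups). The normative reference and
#' the time-out penalty depth are then solved analytically — a 3x3 linear
#' system in the overall-score location, scale, and penalty depth — so
#' that the expected per-group means of the normalized overall score equal
#' the reported overall estimated marginal means (0.71, -2.15, -5.63)
#' exactly, accounting for time-out censoring and the dementia
#' contaminated tail.
#'
#' @param seed Integer seed stored in the config.
#' @return A \code{generator_config} with a \code{"calibration"} attribute
#'   recording the solved constants (per-assessment weight \code{w},
#'   penalty depth \code{r} in normative SDs, overall offset \code{c0}).
#' @export
calibrated_defaults <- function(seed = 1L) {
  k <- study_constants()
  n <- k$group_sizes
  sigma <- rowMeans(sweep(k$assessment_se, 2L, sqrt(n), `*`))
  icc <- 0.6
  timeout_p <- c(NC = 0.05, MCI = 0.20, dementia = 0.45)
  tail <- c(fraction = 0.15, shift = -1.5, inflation = 1.8)

  etil <- k$assessment_effects
  etil[, "dementia"] <- etil[, "dementia"] + tail[["fraction"]] * tail[["shift"]]
  mix_factor <- c(1, 1, 1 + tail[["fraction"]] * (tail[["inflation"]] - 1))
  A <- calibration_design(etil, sigma, timeout_p, mix_factor)
  # Solve c0 + w*A_g - (w*r)*3*p_g = target_g for (c0, w, w*r).
  M <- cbind(1, A, -3 * timeout_p)
  sol <- solve(M, k$overall_emm)
  c0 <- sol[1L]; w <- sol[2L]; r <- sol[3L] / sol[2L]
  if (w <= 0 || r <= 0) {
    stop_validation("calibration produced non-positive weight or penalty depth")
  }

  s <- 10  # native-scale unit per normative SD; any positive value works
  m <- r * s
  sigma_o <- s / (7 * w)
  mu_o <- m - c0 * sigma_o
  ref <- normative_reference(data.frame(
    score_name = rep(SCORE_NAMES, each = 2L),
    age_lo = 40, age_hi = 100,
    device = rep(DEVICE_LEVELS, times = length(SCORE_NAMES)),
    mean = rep(c(rep(m, length(ASSESSMENTS)), mu_o), each = 2L),
    sd = rep(c(rep(s, length(ASSESSMENTS)), sigma_o), each = 2L),
    stringsAsFactors = FALSE
  ))

  sdlog <- log(k$duration_iqr[, "q3"] / k$duration_iqr[, "q1"]) /
    (2 * stats::qnorm(0.75))
  cfg <- generator_config(
    group_sizes = k$group_sizes,
    age_mean_sd = k$age_mean_sd,
    sex_p_female = k$sex_p_female,
    administration_p_remote = k$administration_p_remote,
    device_p_computer = 0.15,
    education_p = k$education_p,
    assessment_effects = k$assessment_effects,
    residual_sd = sigma,
    icc = icc,
    dementia_tail = tail,
    timeout_base_p = timeout_p,
    duration_model = cbind(median = k$duration_median, sdlog = sdlog),
    reference = ref,
    seed = seed
  )
  attr(cfg, "calibration") <- list(w = w, r = r, c0 = c0)
  cfg
}

#' Zero-effect generator configuration
#'
#' The calibrated configuration with every group mean shift removed: no
#' assessment effects, no dementia tail, no time-outs, and identical
#' duration distributions. Under this null, any detected group difference
#' is a false positive, which makes it the reference condition for
#' familywise-error-rate checks.
#'
#' @param seed Integer seed.
#' @return A \code{generator_config}.
#' @export
zero_effect_config <- function(seed = 1L) {
  cfg <- calibrated_defaults(seed)
  cfg$assessment_effects[] <- 0
  cfg$dementia_tail[1L] <- 0
  cfg$timeout_base_p[] <- 0
  cfg$duration_model[, "median"] <- mean(cfg$duration_model[, "median"])
  cfg$duration_model[, "sdlog"] <- mean(cfg$duration_model[, "sdlog"])
  attr(cfg, "calibration") <- NULL
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a \code{\link{generator_config}}: exact group
#' sizes, group-specific demographics, raw assessment scores built from
#' normative entries plus calibrated z shifts and correlated residuals,
#' quantile-censored time-outs for the timed assessments, and log-normal
#' battery durations. Bit-reproducible from the config (including its
#' seed).
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{\link{cohort}}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  ref <- config$reference
  bands <- attr(ref, "age_bands")
  age_min <- bands$age_lo[1L]
  age_max <- bands$age_hi[nrow(bands)]
  f <- config$dementia_tail[1L]
  delta <- config$dementia_tail[2L]
  lambda <- config$dementia_tail[3L]
  icc <- config$icc

  with_seed(config$seed, {
    rows <- lapply(DIAGNOSIS_LEVELS, function(g) {
      ng <- config$group_sizes[[g]]
      if (ng == 0L) return(NULL)
      age <- stats::rnorm(ng, config$age_mean_sd[g, "mean"],
                          config$age_mean_sd[g, "sd"])
      # keep ages inside the normative bands so scoring never clamps
      age <- pmin(pmax(age, age_min), age_max - 0.01)
      df <- data.frame(
        id = sprintf("%s-%03d", g, seq_len(ng)),
        age = age,
        sex = ifelse(stats::runif(ng) < config$sex_p_female[[g]],
                     "female", "male"),
        education = sample(EDUCATION_LEVELS, ng, replace = TRUE,
                           prob = config$education_p[, g]),
        administration = ifelse(
          stats::runif(ng) < config$administration_p_remote[[g]],
          "remote", "on-site"),
        device = ifelse(stats::runif(ng) < config$device_p_computer,
                        "computer", "ipad"),
        diagnosis = g,
        battery_duration_min = stats::rlnorm(
          ng, log(config$duration_model[g, "median"]),
          config$duration_model[g, "sdlog"]),
        stringsAsFactors = FALSE
      )
      eta <- stats::rnorm(ng)
      contaminated <- if (g == "dementia") stats::runif(ng) < f else rep(FALSE, ng)
      p_to <- config$timeout_base_p[[g]]
      for (j in seq_along(ASSESSMENTS)) {
        a <- ASSESSMENTS[j]
        resid <- sqrt(icc) * eta + sqrt(1 - icc) * stats::rnorm(ng)
        sd_j <- config$residual_sd[j] * ifelse(contaminated, lambda, 1)
        shift <- config$assessment_effects[j, g] +
          ifelse(contaminated, delta, 0)
        zlat <- shift + sd_j * resid
        timed_out <- if (a %in% TIMED_ASSESSMENTS) {
          stats::pnorm(resid) < p_to
        } else rep(FALSE, ng)
        raw <- vapply(seq_len(ng), function(i) {
          entry <- normative_lookup(ref, a, df$age[i], df$device[i])
          max(entry$mean + entry$sd * zlat[i], 0)
        }, numeric(1L))
        raw[timed_out] <- NA_real_
        df[[paste0(a, "_raw")]] <- raw
        df[[paste0(a, "_timed_out")]] <- timed_out
        df[[paste0(a, "_duration_s")]] <- ifelse(
          timed_out, 30 * stats::runif(ng, 1, 3),
          stats::rlnorm(ng, log(60), 0.4))
      }
      df
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) stop_validation("all group sizes are zero")
    cohort(df, provenance = sprintf("generate_cohort(seed=%d)", config$seed))
  })
}
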