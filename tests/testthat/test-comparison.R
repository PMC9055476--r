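test_that("the IQR filter keeps values inside the Tukey fences", {
  expect_equal(iqr_filter(c(1, 2, 3, 4, 5)), c(1, 2, 3, 4, 5))
  # type-7 quartiles of (0,0,0,0,10) are both 0: fences collapse to [0,0]
  expect_equal(iqr_filter(c(0, 0, 0, 0, 10)), c(0, 0, 0, 0))
  expect_equal(iqr_filter(rep(3.2, 6)), rep(3.2, 6))
  expect_error(iqr_filter(c(1, 2, 3)), class = "cogdx_validation_error")
  # order of survivors is preserved
  expect_equal(iqr_filter(c(5, 1, 100, 2, 4, 3)), c(5, 1, 2, 4, 3))
})

test_that("the adjusted model recovers a constructed linear system exactly", {
  frame <- balanced_frame(per_cell = 2L, group_means = c(1, 3, 7))
  # add exact covariate effects so every coefficient is known
  frame$y <- frame$y + 0.5 * frame$age + 2 * (frame$sex == "male") -
    1.5 * (frame$administration == "remote")
  fit <- fit_adjusted_model(frame, "y")
  cf <- coef(fit)
  expect_equal(unname(cf[["diagnosisMCI"]]), 2, tolerance = 1e-10)
  expect_equal(unname(cf[["diagnosisdementia"]]), 6, tolerance = 1e-10)
  expect_equal(unname(cf[["age"]]), 0.5, tolerance = 1e-10)
  expect_equal(unname(cf[["sexmale"]]), 2, tolerance = 1e-10)
  expect_equal(unname(cf[["administrationremote"]]), -1.5, tolerance = 1e-10)
})

test_that("coefficients are invariant under record duplication", {
  set.seed(8)
  frame <- balanced_frame(per_cell = 3L)
  frame$y <- frame$y + rnorm(nrow(frame))
  fit1 <- fit_adjusted_model(frame, "y")
  fit2 <- fit_adjusted_model(rbind(frame, frame), "y")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)
  expect_gt(fit2$residual_df, fit1$residual_df)
})

test_that("a single-group frame is rejected", {
  frame <- balanced_frame()
  frame <- frame[frame$diagnosis == "NC", ]
  expect_error(fit_adjusted_model(frame, "y"),
               class = "cogdx_validation_error")
})

test_that("EMMs equal raw group means on balanced covariate-free designs", {
  set.seed(5)
  frame <- balanced_frame(per_cell = 4L)
  frame$y <- frame$y + rnorm(nrow(frame), sd = 0.5)
  fit <- fit_adjusted_model(frame, "y")
  emm <- estimated_marginal_means(fit)
  raw <- tapply(frame$y, factor(frame$diagnosis, diagnosis_levels()), mean)
  expect_equal(emm$emm, as.vector(raw[emm$group]), tolerance = 1e-10)
})

test_that("EMMs match the hand-computed linear combination of coefficients", {
  set.seed(6)
  frame <- balanced_frame(per_cell = 3L)
  frame$y <- frame$y + 0.3 * frame$age + rnorm(nrow(frame))
  fit <- fit_adjusted_model(frame, "y")
  emm <- estimated_marginal_means(fit)
  cf <- coef(fit)
  base <- cf[["(Intercept)"]] + cf[["age"]] * mean(frame$age) +
    cf[["sexmale"]] / 2 + cf[["administrationremote"]] / 2
  expect_equal(emm$emm[emm$group == "NC"], unname(base), tolerance = 1e-10)
  expect_equal(emm$emm[emm$group == "MCI"],
               unname(base + cf[["diagnosisMCI"]]), tolerance = 1e-10)
  expect_equal(emm$emm[emm$group == "dementia"],
               unname(base + cf[["diagnosisdementia"]]), tolerance = 1e-10)
})

test_that("EMMs are invariant to a constant age shift", {
  set.seed(7)
  frame <- balanced_frame(per_cell = 3L)
  frame$y <- frame$y + 0.3 * frame$age + rnorm(nrow(frame))
  emm1 <- estimated_marginal_means(fit_adjusted_model(frame, "y"))
  frame2 <- frame
  frame2$age <- frame2$age + 10
  frame2$y <- frame2$y  # outcome unchanged; prediction at the new mean
  emm2 <- estimated_marginal_means(fit_adjusted_model(frame2, "y"))
  expect_equal(emm1$emm, emm2$emm, tolerance = 1e-10)
})

test_that("Tukey contrasts agree with a direct studentized-range computation", {
  set.seed(9)
  frame <- balanced_frame(per_cell = 4L, group_means = c(0, -1, -2.5))
  frame$y <- frame$y + rnorm(nrow(frame))
  fit <- fit_adjusted_model(frame, "y")
  emm <- estimated_marginal_means(fit)
  ct <- tukey_contrasts(fit, emm)
  # independent oracle: p = P(q_{3, df} >= sqrt(2) |t|)
  for (i in seq_len(nrow(ct))) {
    t_stat <- ct$estimate[i] / ct$se[i]
    p_oracle <- ptukey(sqrt(2) * abs(t_stat), nmeans = 3, df = ct$df[i],
                       lower.tail = FALSE)
    expect_equal(ct$p_adjusted[i], p_oracle, tolerance = 1e-10)
    expect_equal(ct$t_ratio[i], t_stat, tolerance = 1e-10)
  }
  # estimates are EMM differences, severe minus less severe
  e <- setNames(emm$emm, emm$group)
  expect_equal(ct$estimate,
               unname(pairwise_contrast_estimates(e)), tolerance = 1e-12)
})

test_that("contrast additivity holds to machine precision on random data", {
  for (seed in 1:5) {
    set.seed(seed)
    frame <- balanced_frame(per_cell = 3L)
    frame$y <- rnorm(nrow(frame), sd = 2)
    ct <- tukey_contrasts(fit_adjusted_model(frame, "y"))
    expect_equal(ct$estimate[1L], ct$estimate[2L] + ct$estimate[3L],
                 tolerance = 1e-12)
    # adjusted p never below the unadjusted two-sided t p
    p_unadj <- 2 * pt(abs(ct$t_ratio), ct$df, lower.tail = FALSE)
    expect_true(all(ct$p_adjusted >= p_unadj - 1e-12))
  }
})

test_that("Tukey p-values are invariant to group relabeling", {
  set.seed(11)
  frame <- balanced_frame(per_cell = 3L)
  frame$y <- rnorm(nrow(frame))
  ct1 <- tukey_contrasts(fit_adjusted_model(frame, "y"))
  frame2 <- frame
  map <- c(NC = "dementia", MCI = "NC", dementia = "MCI")
  frame2$diagnosis <- unname(map[frame2$diagnosis])
  ct2 <- tukey_contrasts(fit_adjusted_model(frame2, "y"))
  expect_equal(sort(ct1$p_adjusted), sort(ct2$p_adjusted), tolerance = 1e-10)
})

test_that("identical group data yield null contrasts", {
  frame <- balanced_frame(per_cell = 3L, group_means = c(0, 0, 0))
  # outcome depends only on the replicate index (nonlinearly, so it is not
  # collinear with age): every group sees the identical outcome pattern
  frame$y <- c(1, 5, 2)[frame$rep]
  ct <- tukey_contrasts(fit_adjusted_model(frame, "y"))
  expect_equal(ct$estimate, c(0, 0, 0), tolerance = 1e-10)
  expect_true(all(ct$p_adjusted > 0.999))
})

test_that("a two-group cohort cannot enter the three-group contrast machinery", {
  frame <- balanced_frame(per_cell = 3L)
  frame <- frame[frame$diagnosis != "MCI", ]
  frame$y <- frame$y + rnorm(nrow(frame))
  fit <- fit_adjusted_model(frame, "y")
  expect_error(tukey_contrasts(fit), class = "cogdx_validation_error")
})

test_that("demographics tests match hand-computed chi-square and boundary cases", {
  # sex counts per group: female (25, 8, 16), male (10, 14, 26)
  rows <- list()
  k <- 0L
  sexes <- list(NC = c(25, 10), MCI = c(8, 14), dementia = c(16, 26))
  for (g in names(sexes)) {
    for (s in seq_len(sexes[[g]][1L])) {
      k <- k + 1L
      rows[[k]] <- make_row(id = paste0("f", k), diagnosis = g, sex = "female")
    }
    for (s in seq_len(sexes[[g]][2L])) {
      k <- k + 1L
      rows[[k]] <- make_row(id = paste0("m", k), diagnosis = g, sex = "male")
    }
  }
  coh <- cohort(do.call(rbind, rows))
  tab <- demographics_table(coh)
  sex_row <- tab[tab$variable == "sex", ]
  # independent oracle: Pearson chi-square from the printed counts
  O <- rbind(c(25, 8, 16), c(10, 14, 26))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  expect_equal(sex_row$statistic, chi2, tolerance = 1e-10)
  expect_equal(sex_row$df, 2)
  expect_equal(round(sex_row$p_value, 3), 0.005)

  # identical categorical distributions give statistic 0, p = 1
  coh2 <- make_cohort(10L)
  tab2 <- demographics_table(coh2)
  adm <- tab2[tab2$variable == "administration", ]
  expect_true(is.na(adm$statistic)) # single observed level: no test possible
})

test_that("identical sex distributions give a zero statistic and p = 1", {
  rows <- list(); k <- 0L
  for (g in diagnosis_levels()) for (s in c("female", "male")) {
    for (i in 1:5) {
      k <- k + 1L
      rows[[k]] <- make_row(id = paste(g, s, i), diagnosis = g, sex = s)
    }
  }
  tab <- demographics_table(cohort(do.call(rbind, rows)))
  sex_row <- tab[tab$variable == "sex", ]
  expect_equal(sex_row$statistic, 0)
  expect_equal(sex_row$p_value, 1)
})

test_that("duration comparison detects the generated slow-down with impairment", {
  cfg <- calibrated_defaults(seed = 17)
  cfg$group_sizes <- cfg$group_sizes * 5L
  coh <- generate_cohort(cfg)
  cmp <- compare_durations(coh)
  e <- setNames(cmp$emm$emm, cmp$emm$group)
  expect_gt(e[["dementia"]], e[["MCI"]])
  expect_gt(e[["MCI"]], e[["NC"]])
  expect_lt(cmp$contrasts$p_adjusted[1L], 0.05)
})

test_that("constant durations produce zero contrasts", {
  rows <- list(); k <- 0L
  for (g in diagnosis_levels()) for (i in 1:4) {
    k <- k + 1L
    rows[[k]] <- make_row(id = paste(g, i), diagnosis = g, age = 60 + i,
                          sex = c("female", "male")[1 + i %% 2],
                          battery_duration_min = 20)
  }
  cmp <- compare_durations(cohort(do.call(rbind, rows)))
  expect_equal(cmp$contrasts$estimate, c(0, 0, 0), tolerance = 1e-10)
})

test_that("IQR filtering inside compare_groups drops flagged outliers", {
  set.seed(15)
  frame <- balanced_frame(per_cell = 4L)
  frame$y <- frame$y + rnorm(nrow(frame), sd = 0.3)
  frame$y[1L] <- 50  # gross outlier
  cmp <- compare_groups(frame, "y", iqr = TRUE)
  expect_equal(cmp$n_removed, 1L)
  expect_equal(nrow(cmp$fit$frame), nrow(frame) - 1L)
})
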