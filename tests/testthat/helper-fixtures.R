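# Fixtures are built in code; nothing is read from disk.

ASSESS <- assessments()

# Single-band reference with distinct per-assessment means so that
# hand-computed examples are non-trivial: assessment j has mean 10*j,
# sd 5; the "overall" entry has mean 35, sd 5. A participant scoring
# exactly the means has battery average mean(10*(1:7)) = 40 and
# overall_z (40 - 35)/5 = 1.
tiny_reference <- function() {
  normative_reference(data.frame(
    score_name = rep(c(ASSESS, "overall"), each = 2L),
    age_lo = 40, age_hi = 100,
    device = rep(c("ipad", "computer"), times = 8L),
    mean = rep(c(10 * seq_along(ASSESS), 35), each = 2L),
    sd = 5,
    stringsAsFactors = FALSE
  ))
}

# One wide cohort row with overridable fields.
make_row <- function(id = "p1", diagnosis = "NC", age = 70, sex = "female",
                     education = "bachelor", administration = "on-site",
                     device = "ipad", battery_duration_min = 20,
                     raw = 10 * seq_along(ASSESS),
                     timed_out = rep(FALSE, length(ASSESS))) {
  row <- data.frame(id = id, age = age, sex = sex, education = education,
                    administration = administration, device = device,
                    diagnosis = diagnosis,
                    battery_duration_min = battery_duration_min,
                    stringsAsFactors = FALSE)
  for (j in seq_along(ASSESS)) {
    row[[paste0(ASSESS[j], "_raw")]] <- if (timed_out[j]) NA_real_ else raw[j]
    row[[paste0(ASSESS[j], "_timed_out")]] <- timed_out[j]
    row[[paste0(ASSESS[j], "_duration_s")]] <- 60
  }
  row
}

make_cohort <- function(n_per_group = 1L, seed = NULL) {
  rows <- list()
  i <- 0L
  for (g in diagnosis_levels()) {
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      rows[[i]] <- make_row(id = sprintf("%s-%d", g, k), diagnosis = g)
    }
  }
  cohort(do.call(rbind, rows))
}

# Randomized valid cohort for round-trip property tests.
random_cohort <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    timed <- ASSESS %in% timed_assessments() & runif(length(ASSESS)) < 0.3
    make_row(
      id = sprintf("r%03d", i),
      diagnosis = sample(diagnosis_levels(), 1L),
      age = runif(1, 45, 95),
      sex = sample(c("female", "male"), 1L),
      education = sample(c("some college or less", "bachelor",
                           "post-bachelor", "NA"), 1L),
      administration = sample(c("on-site", "remote"), 1L),
      device = sample(c("ipad", "computer"), 1L),
      battery_duration_min = runif(1, 10, 45),
      raw = round(runif(length(ASSESS), 0, 120), 6),
      timed_out = timed
    )
  })
  cohort(do.call(rbind, rows))
}

# Small scored-cohort-like frame for model tests: balanced 3 groups x
# sex x administration, ages repeated identically per cell, outcome an
# exact function of group (covariates carry zero effect).
balanced_frame <- function(per_cell = 2L, group_means = c(0, -2, -5)) {
  grid <- expand.grid(
    diagnosis = diagnosis_levels(),
    sex = c("female", "male"),
    administration = c("on-site", "remote"),
    rep = seq_len(per_cell),
    stringsAsFactors = FALSE
  )
  grid$age <- 60 + 5 * grid$rep
  grid$y <- group_means[match(grid$diagnosis, diagnosis_levels())]
  grid
}

temp_csv <- function() tempfile(fileext = ".csv")
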