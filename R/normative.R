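#' Normative reference tables
#'
#' A normative reference maps \code{(score_name, age_band, device)} to the
#' mean and SD of that score in a healthy reference population. Scoring
#' standardizes raw scores as \code{(raw - mean) / sd} against the entry
#' resolved for the participant's age and device. Age bands are half-open
#' intervals \code{[lo, hi)}; an age outside the covered range clamps to
#' the nearest band with a warning, so scoring is total.
#'
#' @param entries Data frame with columns \code{score_name}, \code{age_lo},
#'   \code{age_hi}, \code{device}, \code{mean}, \code{sd}. Every combination
#'   of score (seven assessments plus \code{"overall"}), age band and device
#'   present in the table must be fully crossed.
#' @return An object of class \code{normative_ref} (a validated data frame).
#' @examples
#' ref <- normative_reference(data.frame(
#'   score_name = rep(c(assessments(), "overall"), 2),
#'   age_lo = 40, age_hi = 100,
#'   device = rep(c("ipad", "computer"), each = 8),
#'   mean = 100, sd = 10
#' ))
#' normative_lookup(ref, "stroop", age = 71, device = "ipad")
#' @export
normative_reference <- function(entries) {
  required <- c("score_name", "age_lo", "age_hi", "device", "mean", "sd")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    stop_schema("normative reference is missing column(s): %s",
                paste(missing, collapse = ", "))
  }
  entries <- as.data.frame(entries)[required]
  entries$score_name <- as.character(entries$score_name)
  entries$device <- as.character(entries$device)
  check_level(entries$score_name, SCORE_NAMES, "score_name", where = "entry")
  check_level(entries$device, DEVICE_LEVELS, "device", where = "entry")
  if (any(!is.finite(entries$sd)) || any(entries$sd <= 0)) {
    bad <- which(!is.finite(entries$sd) | entries$sd <= 0)[1L]
    stop_validation("normative sd must be > 0 (entry %d has sd = %s)",
                    bad, format(entries$sd[bad]))
  }
  if (any(entries$age_hi <= entries$age_lo)) {
    stop_validation("age bands must satisfy lo < hi")
  }

  bands <- unique(entries[c("age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), , drop = FALSE]
  if (nrow(bands) > 1L) {
    for (i in seq_len(nrow(bands) - 1L)) {
      if (bands$age_hi[i] > bands$age_lo[i + 1L]) {
        stop_validation("age bands [%g,%g) and [%g,%g) overlap",
                        bands$age_lo[i], bands$age_hi[i],
                        bands$age_lo[i + 1L], bands$age_hi[i + 1L])
      }
      if (bands$age_hi[i] < bands$age_lo[i + 1L]) {
        stop_validation("age bands leave a gap between %g and %g",
                        bands$age_hi[i], bands$age_lo[i + 1L])
      }
    }
  }

  scores <- unique(entries$score_name)
  devices <- unique(entries$device)
  key <- with(entries, paste(score_name, age_lo, age_hi, device, sep = "|"))
  if (anyDuplicated(key)) {
    stop_validation("duplicate normative entry: %s", key[duplicated(key)][1L])
  }
  grid <- expand.grid(score = scores, band = seq_len(nrow(bands)),
                      device = devices, stringsAsFactors = FALSE)
  want <- paste(grid$score, bands$age_lo[grid$band], bands$age_hi[grid$band],
                grid$device, sep = "|")
  absent <- setdiff(want, key)
  if (length(absent)) {
    stop_completeness("normative grid is incomplete; missing cell (%s)",
                      gsub("\\|", ", ", absent[1L]))
  }

  rownames(entries) <- NULL
  structure(entries, class = c("normative_ref", "data.frame"),
            age_bands = bands)
}

#' @export
print.normative_ref <- function(x, ...) {
  bands <- attr(x, "age_bands")
  cat(sprintf("Normative reference: %d entries, %d age band(s), devices: %s\n",
              nrow(x), nrow(bands),
              paste(unique(x$device), collapse = ", ")))
  invisible(x)
}

#' Resolve a normative entry
#'
#' Looks up the \code{(mean, sd)} entry for a score at a given age and
#' device. Bands are half-open \code{[lo, hi)}; ages below or above the
#' covered range clamp to the first or last band with a warning.
#'
#' @param ref A \code{\link{normative_reference}}.
#' @param score_name One of the seven assessments or \code{"overall"}.
#' @param age Age in years.
#' @param device \code{"ipad"} or \code{"computer"}.
#' @return A list with elements \code{mean} and \code{sd}.
#' @export
normative_lookup <- function(ref, score_name, age, device) {
  stopifnot(inherits(ref, "normative_ref"))
  check_level(score_name, SCORE_NAMES, "score_name")
  check_level(device, DEVICE_LEVELS, "device")
  bands <- attr(ref, "age_bands")
  if (age < bands$age_lo[1L]) {
    warning(sprintf("age %g below covered range; clamped to band [%g,%g)",
                    age, bands$age_lo[1L], bands$age_hi[1L]))
    i <- 1L
  } else if (age >= bands$age_hi[nrow(bands)]) {
    if (age > bands$age_hi[nrow(bands)]) {
      warning(sprintf("age %g above covered range; clamped to band [%g,%g)",
                      age, bands$age_lo[nrow(bands)], bands$age_hi[nrow(bands)]))
    }
    i <- nrow(bands)
  } else {
    i <- which(age >= bands$age_lo & age < bands$age_hi)
  }
  hit <- ref$score_name == score_name & ref$device == device &
    ref$age_lo == bands$age_lo[i] & ref$age_hi == bands$age_hi[i]
  if (sum(hit) != 1L) {
    stop_completeness("no normative entry for (%s, [%g,%g), %s)",
                      score_name, bands$age_lo[i], bands$age_hi[i], device)
  }
  list(mean = ref$mean[hit], sd = ref$sd[hit])
}

#' Read / write a normative reference CSV
#'
#' CSV columns: \code{score_name, age_lo, age_hi, device, mean, sd}
#' (comma-separated, UTF-8, \code{.} decimal, header required).
#'
#' @param path File path.
#' @return \code{read_normative_reference}: a \code{\link{normative_reference}}.
#'   \code{write_normative_reference}: \code{path}, invisibly.
#' @export
read_normative_reference <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  normative_reference(df)
}

#' @param ref A \code{\link{normative_reference}}.
#' @rdname read_normative_reference
#' @export
write_normative_reference <- function(ref, path) {
  stopifnot(inherits(ref, "normative_ref"))
  out <- as.data.frame(ref)
  for (col in c("age_lo", "age_hi", "mean", "sd")) out[[col]] <- format_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Generate a synthetic normative reference
#'
#' Stand-in for an unpublished normative database: draws a plausible mean
#' and SD for every (score, age band, device) cell. Deterministic given the
#' seed. Intended for exercising the scoring and analysis machinery, not
#' for emulating any particular instrument's norms.
#'
#' @param age_bands List (or 2-column matrix) of \code{c(lo, hi)} half-open
#'   age intervals, in years, contiguous and increasing.
#' @param devices Character vector of device labels (subset of
#'   \code{"ipad"}, \code{"computer"}).
#' @param seed Integer seed.
#' @return A \code{\link{normative_reference}}.
#' @export
generate_normative_reference <- function(age_bands, devices = DEVICE_LEVELS,
                                         seed = 1L) {
  if (length(age_bands) == 0L) stop_validation("age_bands must be nonempty")
  if (is.matrix(age_bands)) {
    age_bands <- lapply(seq_len(nrow(age_bands)), function(i) age_bands[i, ])
  }
  check_level(devices, DEVICE_LEVELS, "device")
  with_seed(seed, {
    grid <- expand.grid(score_name = SCORE_NAMES,
                        band = seq_along(age_bands),
                        device = devices,
                        stringsAsFactors = FALSE)
    entries <- data.frame(
      score_name = grid$score_name,
      age_lo = vapply(age_bands[grid$band], `[`, numeric(1L), 1L),
      age_hi = vapply(age_bands[grid$band], `[`, numeric(1L), 2L),
      device = grid$device,
      mean = stats::runif(nrow(grid), 40, 120),
      sd = stats::runif(nrow(grid), 5, 20),
      stringsAsFactors = FALSE
    )
    normative_reference(entries)
  })
}
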