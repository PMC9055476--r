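# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user streams.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_cogdx <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "cogdx_error"),
                      call = sys.call(-1)))
}

# Validation error: bad values in otherwise well-formed input.
stop_validation <- function(fmt, ...) stop_cogdx(fmt, ..., class = "cogdx_validation_error")
# Schema error: structurally wrong input (missing columns etc.).
stop_schema <- function(fmt, ...) stop_cogdx(fmt, ..., class = "cogdx_schema_error")
# Completeness error: a required normative grid cell is missing.
stop_completeness <- function(fmt, ...) stop_cogdx(fmt, ..., class = "cogdx_completeness_error")

check_level <- function(x, levels, what, where = NULL) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    idx <- which(bad)[1L]
    loc <- if (is.null(where)) sprintf("element %d", idx) else sprintf("%s %d", where, idx)
    stop_validation(
      "unknown %s label '%s' at %s; allowed: %s",
      what, x[idx], loc, paste(levels, collapse = ", ")
    )
  }
  invisible(x)
}

# Exact decimal serialization so CSV round-trips are value-identical.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1L))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
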