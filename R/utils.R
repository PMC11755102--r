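#' Round half up
#'
#' Commercial rounding: fractions of exactly .5 round away from zero.
#' Used only at the final reporting step for counts; all chained
#' extrapolations keep unrounded intermediates.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @return numeric vector of the same length with integral values.
#' @examples
#' round_half_up(c(2.5, 2.49, 0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

SEVERITIES <- c("mild", "moderate", "severe")

EMPLOYMENT_CLASSES <- c("full_time", "part_time", "unemployed", "retired_age",
                        "retired_sickness", "student", "other")

ADULT_AGE_BANDS <- c("18-25", "26-35", "36-45", "46-55", "56-65", "66-75", "75+")
PEDIATRIC_AGE_BANDS <- c("1-10", "11-17")

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activity",
                     "pain_discomfort", "anxiety_depression")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && abs(x - round(x)) < 1e-8
}

check_simplex <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) stopf("%s must be non-negative", what)
  if (abs(sum(p) - 1) > tol) stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  invisible(p)
}

named_by_severity <- function(x) {
  if (length(x) != 3L) stopf("expected one value per severity level")
  stats::setNames(as.numeric(x), SEVERITIES)
}
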