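#' Read an EQ-5D-5L value set
#'
#' A value set is a CSV of 20 decrements (columns `dimension`, `level`,
#' `decrement`; levels 2..5 for each of the five dimensions), anchored at
#' utility 1 for state 11111. Decrements must be non-negative and
#' non-decreasing in level within each dimension; the floor (state 55555)
#' is 1 minus the sum of the level-5 decrements and may be negative.
#'
#' @param path CSV path; default is the synthetic tariff packaged with
#'   adcoi (no national Romanian 5L value set exists; the packaged set is a
#'   constructed, documented default so analyses run offline).
#' @return an object of class `eq5d_value_set`: `name`, `anchor`,
#'   `decrements` (5 x 4 matrix, dimensions x levels 2..5), `floor`.
#' @export
read_value_set <- function(path = NULL) {
  name <- if (is.null(path)) "synthetic-default" else
    sub("\\.[^.]*$", "", basename(path))
  path <- path %||% system.file("extdata", "eq5d_valueset_synthetic.csv",
                                package = "adcoi")
  if (!file.exists(path)) stopf("value-set file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tab))) stopf("value set needs columns %s",
                                        paste(need, collapse = ", "))
  dec <- matrix(NA_real_, nrow = 5, ncol = 4,
                dimnames = list(EQ5D_DIMENSIONS, paste0("L", 2:5)))
  for (i in seq_len(nrow(tab))) {
    if (!tab$dimension[i] %in% EQ5D_DIMENSIONS)
      stopf("unknown dimension '%s'", tab$dimension[i])
    if (!tab$level[i] %in% 2:5) stopf("levels must be 2..5")
    dec[tab$dimension[i], tab$level[i] - 1L] <- tab$decrement[i]
  }
  if (anyNA(dec)) stopf("value set is incomplete (20 decrements required)")
  if (any(dec < 0)) stopf("decrements must be non-negative")
  if (any(apply(dec, 1, diff) < -1e-12))
    stopf("decrements must be non-decreasing in level within each dimension")
  structure(list(name = name, anchor = 1.0, decrements = dec,
                 floor = 1.0 - sum(dec[, "L5"])),
            class = "eq5d_value_set")
}

#' @rdname read_value_set
#' @export
default_value_set <- function() read_value_set()

parse_states <- function(states) {
  if (!is.character(states)) states <- as.character(states)
  bad <- !grepl("^[1-5]{5}$", states)
  if (any(bad)) stopf("malformed EQ-5D state(s): %s",
                      paste(unique(states[bad]), collapse = ", "))
  matrix(as.integer(unlist(strsplit(states, ""))), ncol = 5, byrow = TRUE,
         dimnames = list(NULL, EQ5D_DIMENSIONS))
}

#' Score EQ-5D-5L states into utilities
#'
#' Additive scoring: utility = 1 minus the decrement of each dimension's
#' level. State 11111 scores exactly 1; state 55555 scores the value-set
#' floor.
#'
#' @param states character vector of 5-digit states (digits 1..5).
#' @param vs an [read_value_set()] object (default: packaged synthetic set).
#' @return numeric utilities.
#' @export
eq5d_index <- function(states, vs = default_value_set()) {
  lv <- parse_states(states)
  dec_full <- cbind(L1 = 0, vs$decrements)   # level 1 has no decrement
  out <- rep(vs$anchor, nrow(lv))
  for (d in seq_along(EQ5D_DIMENSIONS)) out <- out - dec_full[d, lv[, d]]
  unname(out)
}

#' Dichotomize EQ-5D-5L states into problem flags
#'
#' Level 1 is "no problems"; levels 2-5 are "problems".
#'
#' @param states character vector of 5-digit states.
#' @return logical matrix, one column per dimension, TRUE = problems.
#' @export
eq5d_dichotomize <- function(states) {
  parse_states(states) >= 2L
}

#' Per-group problem frequencies by EQ-5D dimension
#'
#' @param records cohort data.frame with `eq5d_state`.
#' @param grouping name of the grouping column (default `"age_group"`).
#' @return data.frame (group, dimension, problems_pct, no_problems_pct);
#'   the two percentages partition 100% per cell.
#' @export
dimension_frequencies <- function(records, grouping = "age_group") {
  flags <- eq5d_dichotomize(records$eq5d_state)
  groups <- records[[grouping]]
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    f <- flags[groups == g, , drop = FALSE]
    data.frame(group = g, dimension = EQ5D_DIMENSIONS,
               problems_pct = 100 * colMeans(f),
               no_problems_pct = 100 * (1 - colMeans(f)),
               n = nrow(f), row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' EQ-VAS summary by group
#'
#' Mean, sample SD (n-1 denominator), median and quartiles (linear
#' interpolation between closest ranks) of the 0-100 visual-analogue
#' self-rating. Groups of one record report SD as NA with `single_obs`
#' flagged; empty groups are omitted.
#'
#' @param records cohort data.frame with `eq_vas`.
#' @param grouping grouping column name (default `"age_group"`).
#' @return data.frame (group, n, mean, sd, median, p25, p75, single_obs).
#' @export
vas_summary <- function(records, grouping = "age_group") {
  v <- records$eq_vas
  if (any(v < 0 | v > 100, na.rm = TRUE)) stopf("EQ-VAS values must lie in [0, 100]")
  groups <- records[[grouping]]
  keep <- !is.na(v)
  do.call(rbind, lapply(unique(groups[keep]), function(g) {
    x <- v[keep & groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               median = q[2], p25 = q[1], p75 = q[3],
               single_obs = length(x) == 1L,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Utility ranges and means by group
#'
#' @param records cohort data.frame with `eq5d_state`.
#' @param vs a value set.
#' @param grouping grouping column name (default `"severity"`).
#' @return data.frame (group, n, min, max, mean); all utilities lie in
#'   [floor, 1].
#' @export
utility_ranges <- function(records, vs = default_value_set(),
                           grouping = "severity") {
  u <- eq5d_index(records$eq5d_state, vs)
  groups <- records[[grouping]]
  do.call(rbind, lapply(unique(groups), function(g) {
    x <- u[groups == g]
    data.frame(group = g, n = length(x), min = min(x), max = max(x),
               mean = mean(x), row.names = NULL, stringsAsFactors = FALSE)
  }))
}
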