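#' Stratify a national case count by survey severity shares
#'
#' Distributes a national (GBD) case total over severity levels in
#' proportion to the integer survey counts (not the rounded percentages:
#' the integer fractions are what make the published extrapolations exact).
#' Unrounded values sum to the total exactly; reported integers are
#' independent round-half-up of each stratum, so their sum can differ from
#' the total by at most half a count per stratum.
#'
#' @param total national case count (persons).
#' @param severity_counts survey severity counts (mild, moderate, severe).
#' @param n_survey survey size; must equal `sum(severity_counts)`.
#' @return list with `cases_unrounded` and `cases` (named by severity).
#' @export
stratify_cases <- function(total, severity_counts, n_survey) {
  if (total < 0) stopf("total must be non-negative")
  severity_counts <- named_by_severity(severity_counts)
  if (n_survey <= 0) stopf("n_survey must be positive")
  if (abs(sum(severity_counts) - n_survey) > 1e-9)
    stopf("severity_counts sum to %s, not n_survey = %s",
          sum(severity_counts), n_survey)
  unrounded <- total * severity_counts / n_survey
  list(cases_unrounded = unrounded, cases = round_half_up(unrounded))
}

#' Split national hospital discharges by segment and severity
#'
#' Two-stage top-down split of the annual discharge total: first between the
#' pediatric (<20) and adult (20+) segments in proportion to the GBD counts
#' on the chosen epidemiological basis, then across severities via the
#' segment's survey fractions. All intermediates stay unrounded; integers
#' are round-half-up of the chained unrounded value (required to match the
#' published counts).
#'
#' @param discharges annual hospital discharge count.
#' @param epi an [epi_inputs()].
#' @param basis `"prevalence"` or `"incidence"`.
#' @param survey survey severity margins: list with `adult` and `pediatric`
#'   elements, each `list(n=, severity_counts=)` (as [national_inputs()]
#'   returns).
#' @return list per segment (`adult`, `pediatric`) with
#'   `segment_unrounded`, `hospitalizations_unrounded`, `hospitalizations`.
#' @export
split_hospitalizations <- function(discharges, epi, basis = c("prevalence", "incidence"),
                                   survey) {
  basis <- match.arg(basis)
  if (discharges < 0) stopf("discharges must be non-negative")
  seg_counts <- if (basis == "prevalence") {
    c(adult = epi$prevalence_20plus, pediatric = epi$prevalence_under20)
  } else {
    c(adult = epi$incidence_20plus, pediatric = epi$incidence_under20)
  }
  denom <- sum(seg_counts)
  if (denom <= 0) stopf("zero population denominator for basis '%s'", basis)
  out <- list()
  for (seg in c("adult", "pediatric")) {
    seg_share <- discharges * seg_counts[[seg]] / denom
    sc <- named_by_severity(survey[[seg]]$severity_counts)
    unrounded <- seg_share * sc / survey[[seg]]$n
    out[[seg]] <- list(segment_unrounded = seg_share,
                       hospitalizations_unrounded = unrounded,
                       hospitalizations = round_half_up(unrounded))
  }
  out
}

#' Per-severity worker counts
#'
#' Applies survey full-time / part-time employment shares to extrapolated
#' per-severity case counts (for caregivers: caregiver employment shares
#' applied to pediatric case counts). Shares must each lie in [0, 1]; a
#' full-time plus part-time share exceeding 1 for some severity is allowed
#' with a warning, because published national figures themselves overlap in
#' this way.
#'
#' @param cases per-severity case counts (mild, moderate, severe).
#' @param ft_shares,pt_shares per-severity employment shares in [0, 1].
#' @return list with `workers_full_time` and `workers_part_time`
#'   (round-half-up integers, named by severity).
#' @export
worker_counts <- function(cases, ft_shares, pt_shares = rep(0, 3)) {
  cases <- named_by_severity(cases)
  ft_shares <- named_by_severity(ft_shares)
  pt_shares <- named_by_severity(pt_shares)
  if (any(cases < 0)) stopf("cases must be non-negative")
  for (sh in list(ft_shares, pt_shares))
    if (any(sh < 0 | sh > 1)) stopf("employment shares must lie in [0, 1]")
  over <- ft_shares + pt_shares > 1 + 1e-9
  if (any(over))
    warnf("full-time + part-time share exceeds 1 for: %s",
          paste(SEVERITIES[over], collapse = ", "))
  list(workers_full_time = round_half_up(cases * ft_shares),
       workers_part_time = round_half_up(cases * pt_shares))
}

#' Build a full severity stratification for one segment and basis
#'
#' Chains [stratify_cases()], [split_hospitalizations()] and
#' [worker_counts()] into the per-segment object the costing engine
#' consumes.
#'
#' @param segment `"adult"` or `"pediatric"`.
#' @param basis `"prevalence"` or `"incidence"`.
#' @param epi an [epi_inputs()].
#' @param survey survey severity margins (see [split_hospitalizations()]).
#' @param averages a `severity_averages` supplying the full/part-time
#'   employment shares.
#' @return an object of class `severity_stratification`.
#' @export
build_stratification <- function(segment = c("adult", "pediatric"),
                                 basis = c("prevalence", "incidence"),
                                 epi, survey, averages) {
  segment <- match.arg(segment)
  basis <- match.arg(basis)
  total <- epi[[paste0(basis, if (segment == "adult") "_20plus" else "_under20")]]
  sc <- survey[[segment]]
  cs <- stratify_cases(total, sc$severity_counts, sc$n)
  hs <- split_hospitalizations(epi$hospital_discharges_total, epi, basis, survey)[[segment]]
  wc <- suppressWarnings(worker_counts(cs$cases,
                                       averages$employment_shares[, "full_time"],
                                       averages$employment_shares[, "part_time"]))
  structure(list(segment = segment, basis = basis, total = total,
                 cases_unrounded = cs$cases_unrounded, cases = cs$cases,
                 hospitalizations_unrounded = hs$hospitalizations_unrounded,
                 hospitalizations = hs$hospitalizations,
                 workers_full_time = wc$workers_full_time,
                 workers_part_time = wc$workers_part_time),
            class = "severity_stratification")
}

#' Tidy view of a stratification
#'
#' @param strat a `severity_stratification`.
#' @return data.frame (segment, basis, severity, quantity, value).
#' @export
stratification_table <- function(strat) {
  qty <- c("cases_unrounded", "cases", "hospitalizations_unrounded",
           "hospitalizations", "workers_full_time", "workers_part_time")
  do.call(rbind, lapply(qty, function(q)
    data.frame(segment = strat$segment, basis = strat$basis,
               severity = SEVERITIES, quantity = q,
               value = as.numeric(strat[[q]]), stringsAsFactors = FALSE)))
}
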