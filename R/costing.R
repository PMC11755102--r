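#' Convert RON to EUR
#'
#' @param amount amount in RON.
#' @param fx RON per EUR (> 0).
#' @return amount in EUR.
#' @export
ron_to_eur <- function(amount, fx) {
  if (!is.numeric(fx) || any(fx <= 0)) stopf("fx must be strictly positive")
  amount / fx
}

#' Bottom-up component total
#'
#' National total for one cost category: per-patient survey mean times the
#' extrapolated case count.
#'
#' @param mean_cost EUR/year per patient.
#' @param cases extrapolated national case count.
#' @return total EUR.
#' @export
component_total <- function(mean_cost, cases) {
  if (any(mean_cost < 0) || any(cases < 0)) stopf("inputs must be non-negative")
  mean_cost * cases
}

#' Treatment total under the average-prescription scenario
#'
#' Replaces the survey-reported treatment cost with the national annual
#' average prescription value.
#'
#' @param cases extrapolated national case count.
#' @param unit a [unit_costs()].
#' @return total EUR.
#' @export
prescription_treatment_total <- function(cases, unit) {
  if (any(cases < 0)) stopf("cases must be non-negative")
  cases * ron_to_eur(unit$avg_prescription, unit$fx)
}

#' Top-down hospitalization total
#'
#' Hospitalization count (kept unrounded through the chain) times the
#' average length of stay and the per-day tariff for the segment. With
#' `hospital_cost_basis = "per_stay"` the tariff is applied per admission
#' and the length of stay is not used.
#'
#' @param hosp_unrounded hospitalization count (may be fractional).
#' @param segment `"adult"` or `"pediatric"`.
#' @param unit a [unit_costs()].
#' @return total EUR.
#' @export
hospitalization_total <- function(hosp_unrounded, segment = c("adult", "pediatric"),
                                  unit) {
  segment <- match.arg(segment)
  if (any(hosp_unrounded < 0)) stopf("hospitalizations must be non-negative")
  per_day <- if (segment == "adult") unit$hospital_cost_per_day_adult
             else unit$hospital_cost_per_day_pediatric
  alos <- if (segment == "adult") unit$alos_adult else unit$alos_pediatric
  ron <- if (unit$hospital_cost_basis == "per_day") hosp_unrounded * alos * per_day
         else hosp_unrounded * per_day
  ron_to_eur(ron, unit$fx)
}

#' Human-capital productivity (absenteeism) total
#'
#' Workers times mean missed days times the gross daily wage for the wage
#' class: `daily_wage = monthly_wage * 12 / working_days_per_year / fx`.
#' Absenteeism only; presenteeism is not measured.
#'
#' @param workers extrapolated worker count.
#' @param mean_days mean missed days/year.
#' @param employment_class `"full_time"` or `"part_time"`.
#' @param unit a [unit_costs()].
#' @return total EUR.
#' @export
productivity_total <- function(workers, mean_days,
                               employment_class = c("full_time", "part_time"),
                               unit) {
  employment_class <- match.arg(employment_class)
  if (any(workers < 0) || any(mean_days < 0)) stopf("inputs must be non-negative")
  monthly <- if (employment_class == "full_time") unit$gross_monthly_wage
             else unit$part_time_monthly_wage
  daily_wage <- ron_to_eur(monthly * 12 / unit$working_days_per_year, unit$fx)
  workers * mean_days * daily_wage
}

#' Scenario specification
#'
#' One of the four costing scenarios: epidemiological basis (prevalence or
#' incidence) crossed with the treatment-cost source (survey-reported or
#' national average prescription).
#'
#' @param basis `"prevalence"` or `"incidence"`.
#' @param treatment_source `"survey"` or `"prescription"`.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(basis = c("prevalence", "incidence"),
                          treatment_source = c("survey", "prescription")) {
  structure(list(basis = match.arg(basis),
                 treatment_source = match.arg(treatment_source)),
            class = "scenario_spec")
}

COMPONENTS <- c("treatment", "medical_services", "associated",
                "hospitalization", "productivity_ft", "productivity_pt")

#' Run one costing scenario for one population segment
#'
#' Assembles all component totals: bottom-up treatment / medical-services /
#' associated costs (published-average times cases; medical services forced
#' to 0 for the pediatric segment, where it was not collected), top-down
#' hospitalization costs (unrounded counts), and hybrid human-capital
#' productivity costs (extrapolated worker counts times mean missed days
#' times the daily wage). Per-patient averages divide by all cases in the
#' stratum, not only cost-incurring ones.
#'
#' @param spec a [scenario_spec()].
#' @param averages a `severity_averages` for the segment.
#' @param strat a `severity_stratification` for the same segment and basis.
#' @param unit a [unit_costs()].
#' @return an object of class `scenario_result`: `segment`, `basis`,
#'   `treatment_source`, `cells` (6 components x 3 severities matrix, EUR),
#'   `component_totals`, `severity_totals`, `grand_total`, `average_overall`
#'   and `average_by_severity` (EUR/patient/year).
#' @export
run_scenario <- function(spec, averages, strat, unit) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(averages, "severity_averages"),
            inherits(strat, "severity_stratification"))
  if (spec$basis != strat$basis)
    stopf("scenario basis '%s' does not match stratification basis '%s'",
          spec$basis, strat$basis)
  if (averages$segment != strat$segment)
    stopf("averages segment '%s' does not match stratification segment '%s'",
          averages$segment, strat$segment)
  segment <- strat$segment

  cells <- matrix(0, nrow = length(COMPONENTS), ncol = 3,
                  dimnames = list(COMPONENTS, SEVERITIES))
  cells["treatment", ] <- if (spec$treatment_source == "survey") {
    component_total(averages$cost_means[, "treatment"], strat$cases)
  } else {
    prescription_treatment_total(strat$cases, unit)
  }
  cells["medical_services", ] <- if (segment == "pediatric") 0 else
    component_total(averages$cost_means[, "medical_services"], strat$cases)
  cells["associated", ] <- component_total(averages$cost_means[, "associated"],
                                           strat$cases)
  cells["hospitalization", ] <- hospitalization_total(
    strat$hospitalizations_unrounded, segment, unit)
  cells["productivity_ft", ] <- productivity_total(
    strat$workers_full_time, averages$days_by_class[, "full_time"],
    "full_time", unit)
  cells["productivity_pt", ] <- productivity_total(
    strat$workers_part_time, averages$days_by_class[, "part_time"],
    "part_time", unit)

  severity_totals <- colSums(cells)
  grand_total <- sum(cells)
  total_cases <- sum(strat$cases)
  structure(list(segment = segment, basis = spec$basis,
                 treatment_source = spec$treatment_source,
                 cells = cells,
                 component_totals = rowSums(cells),
                 severity_totals = severity_totals,
                 grand_total = grand_total,
                 average_overall = if (total_cases > 0) grand_total / total_cases else NA_real_,
                 average_by_severity = ifelse(strat$cases > 0,
                                              severity_totals / strat$cases, NA_real_)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %s segment, %s basis, %s treatment\n",
              x$segment, x$basis, x$treatment_source))
  cat(sprintf("  grand total EUR %.1f; average/patient EUR %.1f\n",
              x$grand_total, x$average_overall))
  invisible(x)
}

#' Tidy view of a scenario result
#'
#' @param result a `scenario_result`.
#' @return data.frame (segment, basis, treatment_source, severity,
#'   component, total_eur).
#' @export
scenario_table <- function(result) {
  data.frame(segment = result$segment, basis = result$basis,
             treatment_source = result$treatment_source,
             severity = rep(SEVERITIES, each = length(COMPONENTS)),
             component = rep(COMPONENTS, times = 3),
             total_eur = as.numeric(result$cells),
             stringsAsFactors = FALSE)
}
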