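#' National epidemiological inputs
#'
#' GBD crude counts (prevalent and incident cases, split at age 20) plus
#' the annual number of hospital discharges with atopic dermatitis as the
#' primary diagnosis.
#'
#' @param prevalence_under20,prevalence_20plus prevalent persons by age segment.
#' @param incidence_under20,incidence_20plus incident persons by age segment.
#' @param hospital_discharges_total discharges in the reference year.
#' @return an object of class `epi_inputs`.
#' @export
epi_inputs <- function(prevalence_under20, prevalence_20plus,
                       incidence_under20, incidence_20plus,
                       hospital_discharges_total) {
  vals <- list(prevalence_under20 = prevalence_under20,
               prevalence_20plus = prevalence_20plus,
               incidence_under20 = incidence_under20,
               incidence_20plus = incidence_20plus,
               hospital_discharges_total = hospital_discharges_total)
  for (nm in names(vals)) {
    if (!is_count(vals[[nm]])) stopf("epi_inputs: '%s' must be a non-negative integer", nm)
  }
  structure(lapply(vals, as.numeric), class = "epi_inputs")
}

#' Unit costs for the costing engine
#'
#' Wages and the per-day hospital tariff are in RON; the engine converts to
#' EUR with the single exchange-rate scalar `fx`. The printed per-admission
#' hospital figures behave as per-day tariffs when combined with the average
#' length of stay; `hospital_cost_basis = "per_stay"` preserves the literal
#' per-admission reading instead.
#'
#' @param gross_monthly_wage,part_time_monthly_wage RON/month.
#' @param working_days_per_year days.
#' @param alos_adult,alos_pediatric average length of stay, days.
#' @param hospital_cost_per_day_adult,hospital_cost_per_day_pediatric RON.
#' @param avg_prescription RON/year, national average prescription value.
#' @param fx RON per EUR.
#' @param hospital_cost_basis `"per_day"` (default) or `"per_stay"`.
#' @return an object of class `unit_costs`.
#' @export
unit_costs <- function(gross_monthly_wage = 6126,
                       part_time_monthly_wage = 3063,
                       working_days_per_year = 251,
                       alos_adult = 7.95,
                       alos_pediatric = 4.44,
                       hospital_cost_per_day_adult = 1094,
                       hospital_cost_per_day_pediatric = 1012,
                       avg_prescription = 40.4,
                       fx = 4.9315,
                       hospital_cost_basis = c("per_day", "per_stay")) {
  hospital_cost_basis <- match.arg(hospital_cost_basis)
  vals <- list(gross_monthly_wage = gross_monthly_wage,
               part_time_monthly_wage = part_time_monthly_wage,
               working_days_per_year = working_days_per_year,
               alos_adult = alos_adult, alos_pediatric = alos_pediatric,
               hospital_cost_per_day_adult = hospital_cost_per_day_adult,
               hospital_cost_per_day_pediatric = hospital_cost_per_day_pediatric,
               avg_prescription = avg_prescription, fx = fx)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stopf("unit_costs: '%s' must be strictly positive", nm)
  }
  if (part_time_monthly_wage > gross_monthly_wage)
    stopf("unit_costs: part-time wage exceeds the gross monthly wage")
  structure(c(vals, list(hospital_cost_basis = hospital_cost_basis)),
            class = "unit_costs")
}

#' Read the national-inputs configuration
#'
#' Reads the YAML (or JSON) configuration holding the GBD counts, hospital
#' discharges, unit costs and survey severity margins. With no `path`, the
#' configuration packaged with adcoi (the 2022 Romanian study inputs) is used.
#'
#' @param path optional path to a YAML/JSON file.
#' @return a list with elements `epi` ([epi_inputs]), `unit_costs`
#'   ([unit_costs]) and `survey` (severity margins per segment).
#' @export
national_inputs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "national_inputs.yaml", package = "adcoi")
  if (!file.exists(path)) stopf("national inputs file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  epi <- do.call(epi_inputs, raw$epi)
  uc <- do.call(unit_costs, raw$unit_costs)
  survey <- lapply(raw$survey, function(s) {
    counts <- named_by_severity(s$severity_counts)
    n <- s$n_respondents %||% s$n
    if (is.null(n) || sum(counts) != n)
      stopf("survey severity counts (%s) do not sum to n_respondents",
            sum(counts))
    list(n = as.numeric(n), severity_counts = counts)
  })
  list(epi = epi, unit_costs = uc, survey = survey)
}

#' Packaged per-severity survey cost averages
#'
#' The per-severity input cost averages (EUR/year per patient) for the three
#' collected categories: treatment, medical services (adults only; the
#' pediatric survey did not collect it) and associated out-of-pocket costs
#' (transport, accommodation, other).
#'
#' @param segment `"adult"` or `"pediatric"`.
#' @return a 3 x 3 matrix, severities by categories, in EUR/year.
#' @export
study_cost_means <- function(segment = c("adult", "pediatric")) {
  segment <- match.arg(segment)
  path <- system.file("extdata", "cost_averages.csv", package = "adcoi")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$segment == segment, ]
  m <- matrix(0, nrow = 3, ncol = 3,
              dimnames = list(SEVERITIES, c("treatment", "medical_services", "associated")))
  for (i in seq_len(nrow(tab))) m[tab$severity[i], tab$category[i]] <- tab$mean_eur[i]
  m
}

#' Packaged productivity calibration (synthetic)
#'
#' Employment shares and mean missed days per severity and wage class.
#' These are synthetic calibration values back-solved so that the published
#' national worker counts and prevalence-side productivity totals are
#' reproduced; they are fixture data, not survey facts (the underlying
#' survey margins were never published).
#'
#' @param segment `"adult"` or `"pediatric"` (caregivers of pediatric patients).
#' @return a data.frame with columns severity, class, employment_share, mean_days.
#' @export
study_productivity_calibration <- function(segment = c("adult", "pediatric")) {
  segment <- match.arg(segment)
  path <- system.file("extdata", "productivity_calibration_synthetic.csv", package = "adcoi")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab[tab$segment == segment, c("severity", "class", "employment_share", "mean_days")]
}
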