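# adcoi

Severity-stratified cost-of-illness (COI) modelling for atopic dermatitis
(AD) in Romania, reference year 2022. The package is aimed at health
economists and HTA analysts who need a tested, reproducible implementation
of a national burden-of-disease calculation: from patient/caregiver survey
averages and published national inputs (GBD 2021 crude counts, hospital
discharges, wages, tariffs) to severity-stratified case counts, direct
medical, direct non-medical and indirect costs under four scenarios, plus
an EQ-5D-5L utility sub-analysis.

## The model

For each population segment (adults 20+; pediatric <20, caregiver-reported)
and severity stratum *s* ∈ {mild, moderate, severe}:

- **Extrapolation**: N_s = N · n_s / n_survey, where N is the GBD crude
  count on the chosen basis (prevalence or incidence) and n_s the integer
  survey severity count (141/368/113 of 622 adults; 22/21/14 of 57
  caregivers). Counts are rounded half-up at reporting only.
- **Bottom-up components** (treatment, medical services, associated
  out-of-pocket costs): C_{s,k} = c̄_{s,k} · N_s from per-patient survey
  means in EUR/year.
- **Top-down hospitalization**: the 1,209 annual AD discharges are split by
  segment (GBD proportions) then severity (survey fractions), kept
  unrounded, and costed as ALOS × per-day tariff / fx (7.95 d × 1,094
  RON/d adults; 4.44 d × 1,012 RON/d pediatric).
- **Hybrid productivity** (human-capital, absenteeism only):
  workers_s × days_s × wage_daily, with wage_daily = 6,126 × 12 / 251 / fx
  RON for full-time and half for part-time.
- **Four scenarios**: {prevalence, incidence} × {survey-reported treatment
  cost, national average prescription (40.4 RON/yr)}.

A seeded synthetic-survey generator reproduces the study cohorts' published
margins exactly (severity counts, per-severity cost means, EQ-5D
dichotomized frequencies, EQ-VAS moments) and provides a controllable
missing-not-at-random mechanism for the adult treatment-cost column, so the
missingness-diagnosis (Little-type MCAR chi-square + logistic regression)
and PMM chained-equations imputation stages are testable without any
deposited data. See `vignettes/cost-of-illness-methods.Rmd` for the full
methods account.

## Worked example

```r
library(adcoi)

ni <- national_inputs()            # packaged 2022 Romanian inputs
av <- study_averages("adult")      # published per-severity cost averages
st <- build_stratification("adult", "prevalence", ni$epi, ni$survey, av)
st$cases
#>     mild moderate   severe
#>    11969    31239     9592

r <- run_scenario(scenario_spec("prevalence", "survey"), av, st, ni$unit_costs)
r
#> Scenario: adult segment, prevalence basis, survey treatment
#>   grand total EUR 29810199.3; average/patient EUR 564.6
round(r$component_totals, 1)
#>        treatment medical_services       associated  hospitalization
#>        7863706.3        9244901.3        6008006.4         723617.3
#>  productivity_ft  productivity_pt
#>        1431911.9        4538056.1
```

The grand total is the 2022 prevalence-based adult burden in EUR; the
average divides it by all 52,800 extrapolated adult cases. Component totals
decompose it into direct medical (treatment, medical services,
hospitalization), direct non-medical (associated) and indirect
(full-/part-time absenteeism) costs. The severe case count is 9,592 from
the printed integer inputs (52,801 × 113/622 = 9,592.46; the source's
unrounded GBD inputs put this cell at 9,593 — see the methods vignette).

The `analysis/` directory holds the numbered workflow drivers:

```sh
Rscript analysis/01_simulate_survey.R     # seeded study-calibrated cohorts + MNAR pass
Rscript analysis/02_process_survey.R      # missingness diagnosis, imputation, averages
Rscript analysis/03_extrapolate.R         # case / hospitalization / worker counts
Rscript analysis/04_costing_scenarios.R   # 8 scenario results (2 segments x 4 scenarios)
Rscript analysis/05_eq5d.R                # utilities, dichotomized frequencies, EQ-VAS
```

Each writes tidy CSV/JSON under `results/`. `run_pipeline()` runs the same
chain in one call and additionally renders the eleven report tables with a
checksummed manifest.

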