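# National inputs for the 2022 Romanian atopic-dermatitis cost analysis.
# Epidemiology: GBD 2021 crude counts for Romania (both sexes) and national
# hospital discharges with AD as primary diagnosis (L20.8 + L20.9).
epi:
  prevalence_under20: 102783
  prevalence_20plus: 52801
  incidence_under20: 13125
  incidence_20plus: 8516
  hospital_discharges_total: 1209
# Unit costs, reference year 2022. Wages in RON/month; hospital tariffs in
# RON/day (see hospital_cost_basis); prescription in RON/year.
unit_costs:
  gross_monthly_wage: 6126
  part_time_monthly_wage: 3063
  working_days_per_year: 251
  alos_adult: 7.95
  alos_pediatric: 4.44
  hospital_cost_per_day_adult: 1094
  hospital_cost_per_day_pediatric: 1012
  avg_prescription: 40.4
  fx: 4.9315          # RON per EUR, 2022 annual average
  hospital_cost_basis: per_day
# Survey severity margins (counts of respondents by self-rated severity).
survey:
  adult:
    n_respondents: 622
    severity_counts: [141, 368, 113]
  pediatric:
    n_respondents: 57
    severity_counts: [22, 21, 14]
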