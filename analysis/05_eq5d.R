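#!/usr/bin/env Rscript
# Stage 5: EQ-5D-5L sub-analysis on the simulated cohorts.
#
# Scores health states with the packaged synthetic value set (no national
# Romanian 5L tariff exists), dichotomizes each dimension into
# problems / no problems, and summarizes EQ-VAS by age band.

library(adcoi)

adult <- read_cohort("results/cohort_adult.csv")
ped <- read_cohort("results/cohort_pediatric.csv")
vs <- default_value_set()
message(sprintf("value set '%s': anchor %.1f, floor %.3f", vs$name, vs$anchor,
                vs$floor))

for (seg in list(list("adult", adult), list("pediatric", ped))) {
  nm <- seg[[1]]; co <- seg[[2]]
  ut <- utility_ranges(co, vs, grouping = "severity")
  for (i in seq_len(nrow(ut)))
    message(sprintf("%s %-9s utilities in [%.3f, %.3f], mean %.3f (n = %d)",
                    nm, ut$group[i], ut$min[i], ut$max[i], ut$mean[i], ut$n[i]))
  utils::write.csv(ut, sprintf("results/utilities_%s.csv", nm), row.names = FALSE)
  utils::write.csv(dimension_frequencies(co),
                   sprintf("results/eq5d_frequencies_%s.csv", nm), row.names = FALSE)
  utils::write.csv(vas_summary(co),
                   sprintf("results/eq_vas_%s.csv", nm), row.names = FALSE)
}
message("wrote results/utilities_*.csv, results/eq5d_frequencies_*.csv, results/eq_vas_*.csv")
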