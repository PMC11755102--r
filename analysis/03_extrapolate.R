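#!/usr/bin/env Rscript
# Stage 3: extrapolate survey severity shares to national counts.
#
# GBD crude counts are split by the integer survey severity margins
# (unrounded intermediates, round-half-up only at reporting); national
# hospital discharges are apportioned top-down by age segment and severity;
# worker counts apply the full/part-time employment shares of the
# productivity calibration.

library(adcoi)

ni <- national_inputs()
tabs <- list()
for (seg in c("adult", "pediatric")) {
  av <- study_averages(seg)
  for (b in c("prevalence", "incidence")) {
    st <- build_stratification(seg, b, ni$epi, ni$survey, av)
    tabs[[paste(seg, b)]] <- stratification_table(st)
    message(sprintf("%s / %s: cases %s; hospitalizations %s", seg, b,
                    paste(st$cases, collapse = "/"),
                    paste(st$hospitalizations, collapse = "/")))
  }
}
dir.create("results", showWarnings = FALSE)
utils::write.csv(do.call(rbind, tabs), "results/stratifications.csv",
                 row.names = FALSE)
message("wrote results/stratifications.csv")
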