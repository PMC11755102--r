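uc <- unit_costs()

test_that("currency conversion matches the published RON/EUR pairs", {
  expect_equal(ron_to_eur(0, 4.9315), 0)
  expect_equal(ron_to_eur(40.4, 4.9315), 8.19, tolerance = 1e-3)
  expect_equal(ron_to_eur(6126, 4.9315), 1242.27, tolerance = 1e-4)
  expect_error(ron_to_eur(10, 0), "fx")
})

test_that("bottom-up component totals reproduce the published direct-cost cells", {
  expect_lt(rel_err(component_total(266.5, 9593), 2556162.1), 0.001)
  expect_lt(rel_err(component_total(427.3, 25245), 10787181), 0.0001)
  expect_equal(component_total(123.45, 0), 0)
  expect_error(component_total(-1, 10), "non-negative")
})

test_that("prescription-scenario treatment totals reproduce the published cells", {
  expect_lt(rel_err(prescription_treatment_total(11969, uc), 98057), 0.002)
  expect_lt(rel_err(prescription_treatment_total(102783, uc), 842056.5), 0.002)
  expect_equal(prescription_treatment_total(0, uc), 0)
})

test_that("hospitalization totals reproduce the published Table-6 style cells", {
  ni <- study_inputs()
  h <- split_hospitalizations(1209, ni$epi, "prevalence", ni$survey)
  got_adult <- hospitalization_total(h$adult$hospitalizations_unrounded, "adult", uc)
  got_ped <- hospitalization_total(h$pediatric$hospitalizations_unrounded, "pediatric", uc)
  for (i in 1:3) {
    expect_lt(rel_err(got_adult[i], study$hosp_costs_table6$adult_prevalence[i]), 0.002)
    expect_lt(rel_err(got_ped[i], study$hosp_costs_table6$pediatric_prevalence[i]), 0.002)
  }
  expect_equal(hospitalization_total(0, "adult", uc), 0)
  # literal per-admission reading is preserved behind a config flag
  uc_stay <- unit_costs(hospital_cost_basis = "per_stay")
  expect_equal(hospitalization_total(10, "adult", uc_stay), 10 * 1094 / 4.9315)
})

test_that("human-capital productivity totals behave and round-trip", {
  # back-solved round trip: published moderate FT total from published workers
  expect_lt(rel_err(productivity_total(17125, 0.903, "full_time", uc), 918088.9),
            0.001)
  expect_equal(productivity_total(1234, 0, "full_time", uc), 0)
  # part-time wage is half the gross wage
  expect_equal(productivity_total(100, 2, "part_time", uc),
               productivity_total(100, 2, "full_time", uc) / 2)
  expect_error(productivity_total(10, 1, "weekend", uc))
})

scenario_fixture <- function(segment, basis) {
  ni <- study_inputs()
  av <- study_averages(segment)
  st <- build_stratification(segment, basis, ni$epi, ni$survey, av)
  list(ni = ni, av = av, st = st)
}

test_that("the adult prevalence scenario reproduces the published grand total", {
  fx <- scenario_fixture("adult", "prevalence")
  r <- run_scenario(scenario_spec("prevalence", "survey"), fx$av, fx$st,
                    fx$ni$unit_costs)
  expect_lt(rel_err(r$grand_total, 29810077.2), 0.001)
  expect_lt(rel_err(r$average_overall, 564.6), 0.001)
  expect_lt(rel_err(r$average_by_severity[["moderate"]], 550.3), 0.001)
})

test_that("pediatric scenarios force medical services to zero and match the prescription delta", {
  fx <- scenario_fixture("pediatric", "prevalence")
  sv <- run_scenario(scenario_spec("prevalence", "survey"), fx$av, fx$st,
                     fx$ni$unit_costs)
  px <- run_scenario(scenario_spec("prevalence", "prescription"), fx$av, fx$st,
                     fx$ni$unit_costs)
  expect_equal(unname(sv$cells["medical_services", ]), c(0, 0, 0))
  expect_lt(rel_err(px$component_totals[["treatment"]], 842056.5), 0.002)
  # scenario coupling: only the treatment row differs
  expect_equal(sv$cells[-1, ], px$cells[-1, ])
  expect_false(isTRUE(all.equal(sv$cells["treatment", ], px$cells["treatment", ])))
})

test_that("scenario results are additive, homogeneous and currency-order invariant", {
  fx <- scenario_fixture("adult", "incidence")
  r <- run_scenario(scenario_spec("incidence", "survey"), fx$av, fx$st,
                    fx$ni$unit_costs)
  # additivity to < 0.01 EUR
  expect_lt(abs(r$grand_total - sum(r$component_totals)), 0.01)
  expect_lt(abs(r$grand_total - sum(r$severity_totals)), 0.01)

  # homogeneity of degree 1 in all counts
  st2 <- fx$st
  for (f in c("cases", "cases_unrounded", "hospitalizations_unrounded",
              "hospitalizations", "workers_full_time", "workers_part_time"))
    st2[[f]] <- st2[[f]] * 2
  r2 <- run_scenario(scenario_spec("incidence", "survey"), fx$av, st2,
                     fx$ni$unit_costs)
  expect_equal(r2$grand_total, 2 * r$grand_total, tolerance = 1e-12)
  expect_equal(r2$average_overall, r$average_overall, tolerance = 1e-12)

  # computing in RON (fx = 1) then converting equals converting inputs first
  uc_ron <- fx$ni$unit_costs
  uc_ron$fx <- 1
  av_ron <- fx$av
  av_ron$cost_means <- av_ron$cost_means * fx$ni$unit_costs$fx
  r_ron <- run_scenario(scenario_spec("incidence", "survey"), av_ron, fx$st, uc_ron)
  expect_equal(r_ron$grand_total / fx$ni$unit_costs$fx, r$grand_total,
               tolerance = 1e-12)

  # error contracts
  expect_error(run_scenario(scenario_spec("prevalence", "survey"), fx$av, fx$st,
                            fx$ni$unit_costs), "basis")
  avp <- study_averages("pediatric")
  expect_error(run_scenario(scenario_spec("incidence", "survey"), avp, fx$st,
                            fx$ni$unit_costs), "segment")
})

test_that("all-zero averages cost nothing beyond hospitalization", {
  fx <- scenario_fixture("adult", "prevalence")
  av0 <- fx$av
  av0$cost_means[] <- 0
  av0$days_by_class[] <- 0
  r <- run_scenario(scenario_spec("prevalence", "survey"), av0, fx$st,
                    fx$ni$unit_costs)
  expect_true(all(r$cells[setdiff(rownames(r$cells), "hospitalization"), ] == 0))
  st0 <- fx$st
  st0$hospitalizations_unrounded[] <- 0
  r0 <- run_scenario(scenario_spec("prevalence", "survey"), av0, st0,
                     fx$ni$unit_costs)
  expect_equal(r0$grand_total, 0)
})
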