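test_that("round-half-up follows the commercial convention", {
  expect_equal(round_half_up(c(2.5, 2.49, 0.5, 0.499, 3.5)), c(3, 2, 1, 0, 4))
  expect_equal(round_half_up(-2.5), -3)
})

test_that("case stratification reproduces the national severity splits", {
  ni <- study_inputs()
  # unrounded shares always reconstitute the total exactly
  for (tot in c(52801, 8516, 102783, 13125)) {
    s <- stratify_cases(tot, c(141, 368, 113), 622)
    expect_equal(sum(s$cases_unrounded), tot)
  }
  s <- stratify_cases(ni$epi$prevalence_20plus, study$adult_counts, 622)
  # independent round-half-up of 52,801 x (141,368,113)/622; the published
  # severe figure is one higher (9,593), consistent with an unrounded GBD input
  expect_equal(unname(s$cases), c(11969, 31239, 9592))
  expect_equal(unname(stratify_cases(8516, study$adult_counts, 622)$cases),
               study$cases$adult_incidence)
  expect_equal(unname(stratify_cases(102783, study$pediatric_counts, 57)$cases),
               study$cases$pediatric_prevalence)
  expect_equal(unname(stratify_cases(13125, study$pediatric_counts, 57)$cases),
               study$cases$pediatric_incidence)
  # per-basis absolute rounding error never exceeds half a count per stratum
  expect_lte(abs(sum(s$cases) - 52801), 3 / 2)

  expect_equal(unname(stratify_cases(100, c(100, 0, 0), 100)$cases), c(100, 0, 0))
  expect_error(stratify_cases(100, c(1, 2, 3), 0), "n_survey")
})

test_that("hospitalization splitting reproduces the published counts", {
  ni <- study_inputs()
  for (b in c("prevalence", "incidence")) {
    h <- split_hospitalizations(1209, ni$epi, b, ni$survey)
    expect_equal(unname(h$adult$hospitalizations), study$hosp[[paste0("adult_", b)]])
    expect_equal(unname(h$pediatric$hospitalizations),
                 study$hosp[[paste0("pediatric_", b)]])
    # the 6 unrounded severity cells reconstitute the discharge total
    expect_equal(sum(h$adult$hospitalizations_unrounded,
                     h$pediatric$hospitalizations_unrounded), 1209,
                 tolerance = 1e-9)
  }
  h0 <- split_hospitalizations(0, ni$epi, "prevalence", ni$survey)
  expect_equal(unname(h0$adult$hospitalizations), c(0, 0, 0))
  expect_equal(unname(h0$pediatric$hospitalizations), c(0, 0, 0))
})

test_that("worker counts apply survey shares with round-half-up", {
  w <- worker_counts(c(100, 200, 50), ft_shares = c(0.5, 0.25, 0.2))
  expect_equal(unname(w$workers_full_time), c(50, 50, 10))
  expect_equal(unname(w$workers_part_time), c(0, 0, 0))

  # calibration shares reproduce the published national worker counts
  w2 <- worker_counts(c(11969, 31239, 9593), ft_shares = c(0.1807, 0.5482, 0.2710))
  expect_equal(unname(w2$workers_full_time), c(2163, 17125, 2600))

  expect_equal(unname(worker_counts(c(0, 0, 0), c(0.5, 0.5, 0.5))$workers_full_time),
               c(0, 0, 0))
  expect_error(worker_counts(c(1, 1, 1), c(1.2, 0, 0)), "shares")
  # the published figures themselves overlap (FT + PT > cases for some strata)
  expect_warning(worker_counts(c(10, 10, 10), c(0.6, 0.6, 0.6), c(0.6, 0.6, 0.6)),
                 "exceeds 1")
})

test_that("stratification is monotone in the national total", {
  base <- stratify_cases(50000, c(141, 368, 113), 622)$cases
  for (tot in c(50500, 60000, 75000)) {
    bigger <- stratify_cases(tot, c(141, 368, 113), 622)$cases
    expect_true(all(bigger >= base))
    base <- bigger
  }
})

test_that("build_stratification assembles a consistent object", {
  ni <- study_inputs()
  st <- build_stratification("adult", "prevalence", ni$epi, ni$survey,
                             study_averages("adult"))
  expect_s3_class(st, "severity_stratification")
  expect_equal(st$cases, round_half_up(st$cases_unrounded))
  # severe FT is 2599 (not the published 2600) because the severe case count
  # rounds to 9592 from integer inputs
  expect_equal(unname(st$workers_full_time), c(2163, 17125, 2599))
  expect_equal(unname(st$workers_part_time), c(1496, 21477, 1799))
  tab <- stratification_table(st)
  expect_equal(nrow(tab), 18)
  expect_true(all(tab$value >= 0))
})
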