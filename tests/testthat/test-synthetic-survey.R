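test_that("severity margins are honoured exactly and runs are reproducible", {
  spec <- adult_study_spec()
  co <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(co), 622)
  expect_equal(unname(table(co$severity)[c("mild", "moderate", "severe")]),
               unname(c(141, 368, 113)), ignore_attr = TRUE)

  ped <- generate_cohort(pediatric_study_spec(), seed = 1)
  expect_equal(nrow(ped), 57)
  expect_equal(as.vector(table(ped$severity)[c("mild", "moderate", "severe")]),
               c(22, 21, 14))

  co2 <- generate_cohort(spec, seed = 1)
  expect_identical(co, co2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(co, f1); write_cohort(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_cohort(f1)$eq5d_state, co$eq5d_state)

  co3 <- generate_cohort(spec, seed = 2)
  expect_false(identical(co, co3))
})

test_that("an empty cohort spec yields an empty cohort", {
  spec <- adult_study_spec()
  spec$n_total <- 0
  spec$severity_counts[] <- 0
  expect_equal(nrow(generate_cohort(spec, seed = 1)), 0)
})

test_that("exact-mean calibration hits every per-severity category mean", {
  for (make in list(adult_study_spec, pediatric_study_spec)) {
    spec <- make()
    co <- generate_cohort(spec, seed = 3)
    for (s in c("mild", "moderate", "severe")) {
      rows <- co[co$severity == s, ]
      expect_equal(mean(rows$cost_treatment), spec$cost_means[s, "treatment"],
                   tolerance = 1e-9)
      expect_equal(mean(rows$cost_associated), spec$cost_means[s, "associated"],
                   tolerance = 1e-9)
      if (spec$kind == "adult_patient")
        expect_equal(mean(rows$cost_medical_services),
                     spec$cost_means[s, "medical_services"], tolerance = 1e-9)
    }
  }
})

test_that("invalid specs are rejected", {
  spec <- adult_study_spec()
  expect_error(cohort_spec(kind = spec$kind, n_total = 10,
                           severity_counts = c(5, 5, 5),
                           cost_means = spec$cost_means,
                           days_means = spec$days_means,
                           employment_probs = spec$employment_probs,
                           age_probs = spec$age_probs,
                           eq5d_no_problem = spec$eq5d_no_problem,
                           vas_mean = spec$vas_mean, vas_sd = spec$vas_sd),
               "severity_counts")
  bad_means <- spec$cost_means; bad_means[1, 1] <- -5
  expect_error(cohort_spec(kind = spec$kind, n_total = 622,
                           severity_counts = c(141, 368, 113),
                           cost_means = bad_means,
                           days_means = spec$days_means,
                           employment_probs = spec$employment_probs,
                           age_probs = spec$age_probs,
                           eq5d_no_problem = spec$eq5d_no_problem,
                           vas_mean = spec$vas_mean, vas_sd = spec$vas_sd),
               "non-negative")
})

test_that("generated records satisfy the domain invariants", {
  for (sd_ in 1:3) {
    for (make in list(adult_study_spec, pediatric_study_spec)) {
      spec <- make()
      co <- generate_cohort(spec, seed = sd_)
      expect_true(all(co$severity %in% c("mild", "moderate", "severe")))
      expect_true(all(co$employment %in% c("full_time", "part_time", "unemployed",
                                           "retired_age", "retired_sickness",
                                           "student", "other")))
      expect_true(all(co$age_group %in% names(spec$age_probs)))
      expect_true(all(co$cost_treatment >= 0))
      expect_true(all(co$cost_associated >= 0))
      expect_true(all(co$days_missed >= 0))
      expect_true(all(grepl("^[1-5]{5}$", co$eq5d_state)))
      expect_true(all(co$eq_vas >= 0 & co$eq_vas <= 100))
      if (spec$kind == "caregiver_of_pediatric")
        expect_true(all(is.na(co$cost_medical_services)))
      else
        expect_true(all(co$cost_medical_services >= 0))
    }
  }
})

test_that("MNAR injector: degenerate rate, MCAR reduction and positive selection", {
  spec <- adult_study_spec()
  co <- generate_cohort(spec, seed = 1)

  none <- inject_mnar(co, rate = 0, strength = 2, seed = 1)
  expect_identical(none$cost_treatment, co$cost_treatment)
  expect_identical(none$cost_treatment_true, co$cost_treatment)
  expect_error(inject_mnar(co, rate = 1), "rate")

  # large MCAR cohort: missing fraction within 3 binomial SEs of the target,
  # and missingness unrelated to the cost value
  big <- co[rep(seq_len(nrow(co)), length.out = 10000), ]
  big$cost_treatment <- rlnorm(10000, 5, 1)
  mc <- inject_mnar(big, rate = 0.2, strength = 0, seed = 11)
  frac <- mean(is.na(mc$cost_treatment))
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  fit <- glm(is.na(mc$cost_treatment) ~ scale(mc$cost_treatment_true),
             family = binomial())
  expect_lt(abs(coef(fit)[2]), 0.1)

  # positive strength preferentially removes expensive records
  mn <- inject_mnar(big, rate = 0.2, strength = 1.5, seed = 12)
  deleted <- is.na(mn$cost_treatment)
  expect_gt(mean(mn$cost_treatment_true[deleted]),
            mean(mn$cost_treatment_true[!deleted]))
  # determinism
  expect_identical(mn, inject_mnar(big, rate = 0.2, strength = 1.5, seed = 12))
})
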