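vs <- default_value_set()

test_that("the packaged value set is well-formed", {
  expect_equal(vs$anchor, 1.0)
  expect_true(all(vs$decrements >= 0))
  expect_true(all(apply(vs$decrements, 1, diff) >= 0))
  expect_equal(vs$floor, 1 - sum(vs$decrements[, "L5"]), tolerance = 1e-9)
})

test_that("utility scoring matches the additive decomposition", {
  expect_equal(eq5d_index("11111", vs), 1.0)
  expect_equal(eq5d_index("55555", vs), vs$floor)
  expect_equal(eq5d_index("21111", vs), 1 - vs$decrements["mobility", "L2"])
  # the packaged set supports the study's extreme observed utilities
  expect_equal(eq5d_index("45555", vs), 0.017, tolerance = 1e-12)
  expect_equal(eq5d_index("55555", vs), -0.025, tolerance = 1e-12)
  expect_error(eq5d_index("1161"), "malformed")
  expect_error(eq5d_index("61111"), "malformed")
})

test_that("worsening any single dimension never increases the index", {
  set.seed(1)
  for (i in 1:50) {
    lv <- sample(1:4, 5, replace = TRUE)
    state <- paste(lv, collapse = "")
    improvable <- which(lv < 5)
    d <- improvable[sample.int(length(improvable), 1)]
    worse <- lv
    worse[d] <- worse[d] + 1
    expect_lte(eq5d_index(paste(worse, collapse = ""), vs),
               eq5d_index(state, vs))
  }
})

test_that("dichotomization flags problems at levels 2-5 and is index-consistent", {
  expect_equal(unname(eq5d_dichotomize("11111")[1, ]), rep(FALSE, 5))
  expect_equal(unname(eq5d_dichotomize("21345")[1, ]), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  set.seed(2)
  states <- replicate(100, paste(sample(1:5, 5, replace = TRUE), collapse = ""))
  flags <- eq5d_dichotomize(states)
  idx <- eq5d_index(states, vs)
  expect_equal(idx == 1, rowSums(flags) == 0)
  # frequency partition
  co <- generate_cohort(adult_study_spec(), seed = 1)
  fr <- dimension_frequencies(co)
  expect_true(all(abs(fr$problems_pct + fr$no_problems_pct - 100) < 0.01))
})

test_that("EQ-VAS summaries use sample SD and interpolated percentiles", {
  one <- data.frame(age_group = "18-25", eq_vas = 70)
  s <- vas_summary(one)
  expect_equal(s$mean, 70)
  expect_equal(s$median, 70)
  expect_true(is.na(s$sd) && s$single_obs)

  same <- data.frame(age_group = "x", eq_vas = rep(55, 9))
  s2 <- vas_summary(same)
  expect_equal(s2$sd, 0)
  expect_equal(c(s2$p25, s2$median, s2$p75), c(55, 55, 55))

  # calibrated generator reproduces the published band moments
  co <- generate_cohort(adult_study_spec(), seed = 3)
  tab <- vas_summary(co)
  b <- tab[tab$group == "18-25", ]
  expect_equal(b$mean, 67.24, tolerance = 1e-6)
  expect_equal(b$sd, 24.98, tolerance = 1e-6)
  expect_error(vas_summary(data.frame(age_group = "x", eq_vas = 105)), "0, 100")
})

test_that("utility ranges are bounded by the floor and the anchor", {
  rec <- data.frame(severity = "mild", eq5d_state = "11111")
  r <- utility_ranges(rec, vs)
  expect_equal(c(r$min, r$max, r$mean), c(1, 1, 1))

  co <- generate_cohort(adult_study_spec(), seed = 4)
  rr <- utility_ranges(co, vs)
  expect_true(all(rr$min >= vs$floor - 1e-12))
  expect_true(all(rr$max <= 1 + 1e-12))

  # fixture cohort hitting the published mild extremes under the packaged set
  fix <- data.frame(severity = c("mild", "mild"), eq5d_state = c("45555", "11111"))
  rf <- utility_ranges(fix, vs)
  expect_equal(c(rf$min, rf$max), c(0.017, 1))
})
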