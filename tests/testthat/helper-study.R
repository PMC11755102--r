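# Published study quantities used as expected values across the suite.
study <- list(
  adult_counts = c(mild = 141, moderate = 368, severe = 113),     # of 622
  pediatric_counts = c(mild = 22, moderate = 21, severe = 14),    # of 57
  cases = list(
    adult_prevalence = c(11969, 31239, 9593),   # printed; severe from 113/622 rounds to 9592
    adult_incidence = c(1930, 5038, 1547),
    pediatric_prevalence = c(39671, 37867, 25245),
    pediatric_incidence = c(5066, 4836, 3224)),
  hosp = list(
    adult_prevalence = c(93, 243, 75),
    adult_incidence = c(108, 281, 86),
    pediatric_prevalence = c(308, 294, 196),
    pediatric_incidence = c(283, 270, 180)),
  # direct-cost component totals by severity (EUR)
  adult_prev_treatment = c(1392698.1, 3913664.59, 2556162.1),
  adult_prev_prescription = c(98057, 255927.6, 78591.3),
  adult_prev_medical = c(732513.6, 4946243.6, 3567733.1),
  adult_prev_associated = c(852900.2, 3051492.8, 2102900.4),
  pediatric_prev_treatment = c(3547085.3, 4973006.9, 5210755.8),
  pediatric_prev_associated = c(4314982.7, 6691554.2, 10787181),
  # component totals entering the grand-total sums
  adult_prev_components = c(treatment = 7862524.77, medical = 9246490.26,
                            hospitalization = 723643.3, associated = 6007293.39,
                            productivity_ft = 1432069.3, productivity_pt = 4538056.2),
  adult_prev_grand = 29810077.2,
  pediatric_prev_components = c(treatment = 13730848, hospitalization = 727754.2,
                                associated = 21793718, productivity_ft = 22081985.9,
                                productivity_pt = 75301229.4),
  pediatric_prev_grand = 133635535.2,
  # per-patient averages, Tables 1 and 2 (prevalence / incidence, survey treatment)
  table1 = list(prevalence = c(all = 564.6, mild = 284.7, moderate = 550.3, severe = 960.1),
                incidence = c(all = 649.4, mild = 369.6, moderate = 635.2, severe = 1045)),
  table2 = list(prevalence = c(all = 1300.2, mild = 374.9, moderate = 2614.8, severe = 782.2),
                incidence = c(all = 4051.4, mild = 758.12, moderate = 9558.5, severe = 967.4)),
  hosp_costs_table6 = list(adult_prevalence = c(164041.3, 428136.2, 131465.7),
                           pediatric_prevalence = c(280887.6, 268120, 178746.64)))

study_inputs <- function() national_inputs()

rel_err <- function(got, want) abs(got - want) / abs(want)

# small complete multivariate dataset with controllable deletion, for the
# missingness / imputation simulations
make_mvn_with_missing <- function(n, rate, mnar_strength = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 3), n, 3)
  y <- drop(x %*% c(1, 0.5, -0.5)) + stats::rnorm(n)
  dat <- cbind(x1 = x[, 1], x2 = x[, 2], x3 = x[, 3], y = y)
  if (rate > 0) {
    z <- as.numeric(scale(y))
    p <- if (mnar_strength == 0) rep(rate, n) else {
      a <- stats::uniroot(function(a) mean(stats::plogis(a + mnar_strength * z)) - rate,
                          c(-30, 30))$root
      stats::plogis(a + mnar_strength * z)
    }
    dat[stats::runif(n) < p, "y"] <- NA
  }
  dat
}
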