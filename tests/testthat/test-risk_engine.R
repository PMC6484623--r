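test_that("Lung-RADS categories dichotomize correctly and reject unknowns", {
  expect_equal(as.character(lungrads_dichotomize(c("1", "2", "3", "4A", "4B", "4X"))),
               c("negative", "negative", "positive", "positive", "positive",
                 "positive"))
  # case-insensitive, bare 4, numeric input, pass-through of +/- forms
  expect_equal(as.character(lungrads_dichotomize(c("4a", "4x", 4, 1, "+", "neg"))),
               c("positive", "positive", "positive", "negative", "positive",
                 "negative"))
  expect_error(lungrads_dichotomize(c("2", "5")), "5")
  expect_error(lungrads_dichotomize("benign"), "BENIGN")
})

test_that("the eight screening patterns partition onto groups 1-4", {
  pats <- expand.grid(t0 = c("-", "+"), t1 = c("-", "+"), t2 = c("-", "+"),
                      stringsAsFactors = FALSE)
  h <- group_history(pats$t0, pats$t1, pats$t2)
  expected <- data.frame(pattern = c("---", "+--", "-+-", "++-",
                                     "--+", "+-+", "-++", "+++"),
                         group = c(1, 2, 2, 3, 3, 4, 4, 4))
  expect_equal(h$pattern, expected$pattern)
  expect_equal(h$group, expected$group)
  expect_equal(h$level8, 1:8)
  # partition sizes {1, 2, 2, 3}
  expect_equal(as.vector(table(h$group)), c(1, 2, 2, 3))
  # Lung-RADS categories flow through the same grouping
  expect_equal(group_history("4B", "1", "3")$group, 4)
  expect_error(group_history("+", NA, "-"), "complete")
})

test_that("risk prediction reproduces the published worked examples", {
  # 3% base risk with >=2 positives, last positive -> 15% 6-year equivalent
  est <- predict_results_risk(0.03, 4)
  expect_equal(round(100 * est$risk_6yr_equivalent), 15)
  expect_equal(est$base_risk_3yr, 0.015)
  # 2.6% base risk, all negative -> 1.5% to one decimal (the ceiling pair)
  est1 <- predict_results_risk(0.026, 1)
  expect_equal(round(100 * est1$risk_6yr_equivalent, 1), 1.5)
  # frozen full-precision values from direct evaluation of the equation
  expect_equal(est$risk_6yr_equivalent, 0.1455075, tolerance = 1e-6)
  expect_equal(est1$risk_6yr_equivalent, 0.0147316, tolerance = 1e-5)
})

test_that("printed group coefficients reproduce the multivariable ORs", {
  co <- results_model_coef()
  expect_equal(round(exp(co$beta_group[["group2"]]), 2), 1.93)
  expect_equal(round(exp(co$beta_group[["group3"]]), 2), 2.66)
  expect_equal(round(exp(co$beta_group[["group4"]]), 2), 8.97)
})

test_that("risk is monotone in base risk and ordered across groups", {
  risks <- seq(0.002, 0.3, length.out = 50)
  for (g in 1:4) {
    out <- predict_results_risk(risks, g, warn_high = FALSE)$risk_3yr
    expect_true(all(diff(out) > 0))
  }
  for (p in c(0.005, 0.015, 0.05, 0.2)) {
    out <- predict_results_risk(p, 1:4, warn_high = FALSE)$risk_3yr
    expect_true(all(diff(out) > 0))
  }
})

test_that("degenerate base risks are rejected, high predictions warned", {
  expect_error(predict_results_risk(0, 1), "0, 1")
  expect_error(predict_results_risk(1, 1), "0, 1")
  expect_error(predict_results_risk(-0.1, 1))
  expect_error(predict_results_risk(0.5, 5), "1..4")
  expect_warning(predict_results_risk(0.29, 4), "12%")
})

test_that("ceiling probabilities match the published decision thresholds", {
  expect_equal(round(100 * ceiling_probability(0.015), 1), 2.6)
  expect_equal(round(100 * ceiling_probability(0.020), 1), 3.4)
})

test_that("ceiling solver and predictor are mutual inverses", {
  for (t in c(0.005, 0.01, 0.015, 0.02, 0.05, 0.09)) {
    p <- ceiling_probability(t)
    back <- predict_results_risk(p, 1, warn_high = FALSE)$risk_6yr_equivalent
    expect_equal(back, t, tolerance = 1e-8)
  }
  # monotone increasing in the threshold
  ts <- seq(0.004, 0.09, length.out = 20)
  expect_true(all(diff(ceiling_probability(ts)) > 0))
  # thresholds beyond the model's reachable range fail explicitly
  expect_error(ceiling_probability(0.5), "not reachable")
})

test_that("ceiling solver falls back to root finding for log-power models", {
  co <- results_model_coef(fp_power = 0, centering = log(0.013),
                           beta_fp = 0.9)
  t <- 0.015
  p <- ceiling_probability(t, co)
  expect_equal(predict_results_risk(p, 1, co)$risk_6yr_equivalent, t,
               tolerance = 1e-8)
})

test_that("eligibility decisions follow the positive-screen and ceiling rules", {
  # base above the 2.6% ceiling, all negative -> continue
  expect_equal(as.character(eligibility_decision(0.03, "-", "-", "-", 0.015)),
               "continue_annual")
  # base below the ceiling, all negative -> consider omitting
  expect_equal(as.character(eligibility_decision(0.016, "-", "-", "-", 0.015)),
               "consider_omit_next")
  # any positive screen -> continue regardless of base risk
  expect_equal(as.character(eligibility_decision(0.016, "+", "-", "-", 0.015)),
               "continue_annual")
  # exactly at the ceiling counts as reached
  ceil <- ceiling_probability(0.015)
  expect_equal(as.character(eligibility_decision(ceil, "-", "-", "-", 0.015)),
               "continue_annual")
})

test_that("coefficient configs round-trip through JSON", {
  co <- results_model_coef()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_coef(co, path)
  co2 <- read_model_coef(path)
  expect_equal(co2, co)
  # the shipped file carries the published model
  shipped <- read_model_coef(system.file("extdata", "plco2012results.json",
                                         package = "lungscreenrisk"))
  expect_equal(shipped$beta_group, co$beta_group)
  expect_equal(shipped$fp_power, -0.5)
  # schema violations are named
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"intercept": -4.4}', bad)
  expect_error(read_model_coef(bad), "beta_group")
})
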