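test_that("Brier score matches hand computations", {
  # near-perfect predictions approach 0
  eps <- 1e-6
  ps <- prediction_set(c(1 - eps, eps), c(1, 0))
  expect_equal(brier(ps), eps^2, tolerance = 1e-6)
  # constant 0.5 prediction scores exactly 0.25
  ps50 <- prediction_set(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(brier(ps50), 0.25)
  # hand computation: ((0.2)^2 + (0.2)^2) / 2
  expect_equal(brier(prediction_set(c(0.8, 0.2), c(1, 0))), 0.04)
})

test_that("prediction sets enforce their contract", {
  expect_error(prediction_set(c(0.2, 0.3), c(1, 0, 1)), "equal length")
  expect_error(prediction_set(numeric(0), numeric(0)), "empty")
  expect_error(prediction_set(c(0, 0.5), c(0, 1)), "strictly inside")
  expect_error(prediction_set(c(0.4, 0.5), c(0, 2)), "binary")
})

test_that("AUC equals exhaustive pair enumeration", {
  # perfectly separated scores
  sep <- prediction_set(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(auc(sep), 1.0)
  # all tied scores
  tied <- prediction_set(rep(0.3, 8), rep(c(0, 1), 4))
  expect_equal(auc(tied), 0.5)
  # 3 cases / 3 controls toy set against the 9-pair enumeration
  toy <- prediction_set(c(0.1, 0.4, 0.35, 0.8, 0.35, 0.6),
                        c(0, 0, 0, 1, 1, 1))
  expect_equal(auc(toy), auc_brute(toy$predicted, toy$observed))
  # random sets of varying size and tie structure
  set.seed(31)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    p <- round(runif(n, 0.01, 0.99), sample(c(1, 2, 3), 1)) # force ties
    p <- pmin(pmax(p, 0.01), 0.99)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    ps <- prediction_set(p, y)
    expect_equal(auc(ps), auc_brute(p, y))
  }
  expect_error(auc(prediction_set(c(0.2, 0.3), c(1, 1))), "both")
})

test_that("Spiegelhalter statistic matches the hand-computed example", {
  # numerator (1-.8)(1-1.6) + 3 (0-.2)(1-.4) = -0.48
  # denominator sqrt(.36*.16 + 3*.36*.16) = 0.48 -> z = -1
  ps <- prediction_set(c(0.8, 0.2, 0.2, 0.2), c(1, 0, 0, 0))
  sp <- spiegelhalter(ps)
  expect_equal(sp$z, -1.0, tolerance = 1e-12)
  expect_equal(sp$p, 2 * pnorm(-1), tolerance = 1e-12)
  # undefined when every prediction is one half
  expect_error(spiegelhalter(prediction_set(rep(0.5, 4), c(0, 1, 0, 1))),
               "0.5")
})

test_that("Spiegelhalter is well calibrated under the null", {
  zs <- vapply(1:20, function(s) spiegelhalter(calibrated_ps(10000, s))$z,
               numeric(1))
  expect_true(all(abs(zs) < 4))
  expect_gt(mean(abs(zs) < 2), 0.85) # ~95% expected
})

test_that("calibration-error percentiles see constructed miscalibration", {
  # calibrated by construction: median absolute error near zero
  e <- calibration_error_percentiles(calibrated_ps(50000, 101))
  expect_lt(e[["50%"]], 0.005)
  # uniform +0.05 inflation is recovered as ~0.05 median error
  e_shift <- calibration_error_percentiles(calibrated_ps(50000, 102,
                                                         shift = 0.05))
  expect_lt(abs(e_shift[["50%"]] - 0.05), 0.01)
  # constant prediction at the prevalence is marginally calibrated
  set.seed(103)
  y <- rbinom(20000, 1, 0.3)
  cps <- prediction_set(rep(mean(y), 20000) + runif(20000, -1e-4, 1e-4), y)
  expect_lt(calibration_error_percentiles(cps)[["50%"]], 0.01)
  # refuses to smooth with too few events
  tiny <- prediction_set(runif(30, 0.1, 0.9), c(rep(1, 3), rep(0, 27)))
  expect_error(calibration_error_percentiles(tiny), "at least")
})

test_that("bootstrap BC intervals are reproducible and contain the estimate", {
  ps <- calibrated_ps(500, 7)
  ci1 <- bootstrap_ci(brier, ps, n_resamples = 200, seed = 99)
  ci2 <- bootstrap_ci(brier, ps, n_resamples = 200, seed = 99)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$estimate)
  expect_gte(ci1$upper, ci1$estimate)
  # degenerate data give a zero-width interval
  dg <- prediction_set(rep(0.2, 20), rep(1, 20))
  cid <- bootstrap_ci(brier, dg, n_resamples = 50, seed = 1)
  expect_equal(cid$lower, cid$upper)
  # failing resamples (single-class AUC draws) are redrawn and logged
  small <- prediction_set(c(0.9, 0.1, 0.2, 0.3), c(1, 0, 0, 0))
  ci_auc <- bootstrap_ci(auc, small, n_resamples = 100, seed = 3,
                         max_retries = 1000)
  expect_gt(ci_auc$n_retried, 0)
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(555); before <- runif(1)
  set.seed(555); invisible(bootstrap_ci(brier, ps, 50, seed = 2))
  expect_identical(runif(1), before)
})

test_that("threshold classification matches exhaustive confusion counts", {
  ps <- toy_prediction_set()
  tab <- threshold_classification(ps, c(0.15, 0.5))
  # threshold 0.15: predicted positive {0.2,0.4,0.6,0.9} -> tp=3 fp=1 fn=0 tn=2
  expect_equal(unlist(tab[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 1, fn = 0, tn = 2))
  expect_equal(tab$sensitivity[1], 1)
  expect_equal(tab$specificity[1], 2 / 3)
  expect_equal(tab$ppv[1], 3 / 4)
  # threshold 0.5: positive {0.6, 0.9} -> tp=2 fp=0 fn=1 tn=3
  expect_equal(tab$sensitivity[2], 2 / 3)
  expect_equal(tab$specificity[2], 1)
  # boundary thresholds
  ends <- threshold_classification(ps, c(0, 1))
  expect_equal(ends$sensitivity[1], 1)
  expect_equal(ends$specificity[1], 0)
  expect_equal(ends$sensitivity[2], 0)
  expect_equal(ends$specificity[2], 1)
  # ties at the threshold count as positive
  tie <- threshold_classification(ps, 0.4)
  expect_equal(tie$tp + tie$fp, sum(ps$predicted >= 0.4))
})

test_that("net benefit has the right reference curves and bounds", {
  ps <- toy_prediction_set()
  prev <- mean(ps$observed)
  nb <- net_benefit(ps, c(0.01, 0.1, 0.3, 0.6))
  expect_true(all(nb$treat_none == 0))
  expect_equal(nb$treat_all,
               prev - (1 - prev) * nb$threshold / (1 - nb$threshold))
  # a perfect predictor attains NB = prevalence below the lowest case score
  perf <- prediction_set(c(0.01, 0.02, 0.9, 0.95), c(0, 0, 1, 1))
  nbp <- net_benefit(perf, c(0.05, 0.3, 0.8))
  expect_equal(nbp$net_benefit[1:2], rep(0.5, 2))
  # any model is bounded by the perfect predictor at every threshold
  ts <- seq(0.05, 0.9, by = 0.05)
  nb_model <- net_benefit(ps, ts)$net_benefit
  perfect_same <- prediction_set(ifelse(ps$observed == 1, 0.999, 0.001),
                                 ps$observed)
  nb_perf <- net_benefit(perfect_same, ts)$net_benefit
  expect_true(all(nb_model <= nb_perf + 1e-12))
  expect_error(net_benefit(ps, 1), "strictly inside")
})

test_that("odds ratios from counts reproduce the published table", {
  # 4-level strata against the all-negative reference
  o2 <- odds_ratio_from_counts(43, 2028 - 43, 116, 12223 - 116)
  o3 <- odds_ratio_from_counts(18, 621 - 18, 116, 12107)
  o4 <- odds_ratio_from_counts(31, 280 - 31, 116, 12107)
  expect_equal(round(o2$or, 2), 2.26)
  expect_equal(round(o3$or, 2), 3.12)
  expect_equal(round(o4$or, 2), 12.99)
  expect_equal(round(o4$lower, 2), 8.57)
  expect_equal(round(o4$upper, 2), 19.69)
  # 8-level strata
  o8 <- odds_ratio_from_counts(9, 42 - 9, 116, 12107)
  expect_equal(round(o8$or, 2), 28.46)
  expect_equal(round(o8$lower, 2), 13.32)
  expect_equal(round(o8$upper, 2), 60.83)
  # symmetric table
  expect_equal(odds_ratio_from_counts(5, 5, 5, 5)$or, 1.0)
  # zero cells flag and withhold the CI
  oz <- odds_ratio_from_counts(0, 10, 5, 20)
  expect_true(oz$zero_cell)
  expect_equal(oz$or, 0)
  expect_true(is.na(oz$lower))
})

test_that("validation reports assemble all metrics coherently", {
  ps <- calibrated_ps(3000, 77)
  vr <- validation_report(ps, n_resamples = 100, seed = 5)
  expect_s3_class(vr, "validation_report")
  expect_equal(vr$brier$estimate, brier(ps))
  expect_equal(vr$auc$estimate, auc(ps))
  expect_true(vr$brier$lower <= vr$brier$estimate,
              vr$brier$upper >= vr$brier$estimate)
  expect_equal(vr$mean_observed, mean(ps$observed))
  expect_equal(nrow(vr$classification), 3)
  expect_output(print(vr), "Brier")
})
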