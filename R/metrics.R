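# Discrimination, calibration, classification and decision-analytic
# evaluation of predicted risks.

#' Bundle predictions with observed outcomes
#'
#' @param predicted predicted probabilities, strictly inside (0, 1).
#' @param observed binary 0/1 outcomes, same length.
#' @param id optional identifiers.
#' @return data.frame of class `prediction_set`.
#' @export
prediction_set <- function(predicted, observed, id = NULL) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("empty prediction set", call. = FALSE)
  if (anyNA(predicted) || any(predicted <= 0) || any(predicted >= 1)) {
    stop("predicted probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (!all(observed %in% c(0, 1))) {
    stop("observed outcomes must be binary 0/1", call. = FALSE)
  }
  if (is.null(id)) id <- seq_along(predicted)
  structure(data.frame(id = id, predicted = as.numeric(predicted),
                       observed = as.numeric(observed)),
            class = c("prediction_set", "data.frame"))
}

.as_ps <- function(ps) {
  if (inherits(ps, "prediction_set")) ps else
    stop("expected a prediction_set; see prediction_set()", call. = FALSE)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 is perfect, 0.25 is an uninformative constant 0.5 prediction.
#'
#' @param ps a [prediction_set()].
#' @return the Brier score.
#' @export
brier <- function(ps) {
  ps <- .as_ps(ps)
  mean((ps$predicted - ps$observed)^2)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a randomly chosen case scores
#' higher than a randomly chosen non-case, counting ties as one half.
#'
#' @param ps a [prediction_set()].
#' @return the AUC.
#' @export
auc <- function(ps) {
  ps <- .as_ps(ps)
  n1 <- sum(ps$observed == 1)
  n0 <- sum(ps$observed == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both cases and non-cases", call. = FALSE)
  }
  r <- rank(ps$predicted)
  (sum(r[ps$observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spiegelhalter calibration test
#'
#' Tests whether outcomes are consistent with their predicted probabilities:
#' \deqn{z = \frac{\sum (y_i - p_i)(1 - 2 p_i)}
#'               {\sqrt{\sum (1 - 2 p_i)^2 p_i (1 - p_i)}}}
#' with a two-sided normal p-value. A significant result indicates some
#' miscalibration.
#'
#' @param ps a [prediction_set()].
#' @return list with `z` and `p`.
#' @export
spiegelhalter <- function(ps) {
  ps <- .as_ps(ps)
  p <- ps$predicted; y <- ps$observed
  den <- sum((1 - 2 * p)^2 * p * (1 - p))
  if (den <= 0) {
    stop("Spiegelhalter statistic is undefined: all predictions equal 0.5",
         call. = FALSE)
  }
  z <- sum((y - p) * (1 - 2 * p)) / sqrt(den)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Calibration-error percentiles
#'
#' Smooths the observed event indicator against the predicted probability
#' (local linear regression, loess) and reports percentiles of the absolute
#' difference between the smoothed observed curve and the prediction,
#' evaluated at each record's predicted value. The 50th and 90th percentiles
#' summarize typical and near-worst calibration error.
#'
#' @param ps a [prediction_set()].
#' @param span loess span (default 0.75).
#' @param probs percentiles to report.
#' @param min_events minimum number of events required to smooth.
#' @return named numeric vector of absolute-error percentiles.
#' @export
calibration_error_percentiles <- function(ps, span = 0.75,
                                          probs = c(0.5, 0.9),
                                          min_events = 10) {
  ps <- .as_ps(ps)
  n_events <- sum(ps$observed)
  if (n_events < min_events || n_events == nrow(ps)) {
    stop("calibration smoothing needs at least ", min_events,
         " events and at least one non-event; got ", n_events, " events",
         call. = FALSE)
  }
  fit <- stats::loess(observed ~ predicted, data = ps, span = span,
                      degree = 1, family = "gaussian")
  smoothed <- stats::predict(fit, newdata = ps)
  err <- abs(smoothed - ps$predicted)
  stats::quantile(err, probs = probs, names = TRUE, na.rm = TRUE)
}

#' Bias-corrected percentile bootstrap interval
#'
#' Resamples records with replacement, computes the statistic on each
#' resample, and returns the bias-corrected (BC, without acceleration)
#' percentile interval. Deterministic under a fixed seed. A resample on
#' which the statistic fails (e.g. a single-class resample for the AUC) is
#' redrawn, up to `max_retries` times in total.
#'
#' @param statistic function of a `prediction_set` returning one number.
#' @param ps a [prediction_set()].
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed (required, no hidden global state).
#' @param conf confidence level.
#' @param max_retries total redraw budget across failing resamples.
#' @return list with `estimate`, `lower`, `upper`, `n_resamples`,
#'   `n_retried`.
#' @export
bootstrap_ci <- function(statistic, ps, n_resamples = 1000, seed,
                         conf = 0.95, max_retries = 100) {
  ps <- .as_ps(ps)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  est <- statistic(ps)
  n <- nrow(ps)
  # restore the caller's RNG state afterwards: no hidden global side effects
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  stats <- numeric(n_resamples)
  retried <- 0L
  for (b in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(statistic(ps[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(val)) break
      retried <- retried + 1L
      if (retried > max_retries) {
        stop("statistic failed on more than ", max_retries,
             " bootstrap resamples", call. = FALSE)
      }
    }
    stats[b] <- val
  }
  if (all(stats == stats[1L])) {
    lo <- hi <- stats[1L] # degenerate data: zero-width interval
  } else {
    prop_below <- mean(stats < est) + 0.5 * mean(stats == est)
    prop_below <- min(max(prop_below, 1 / (2 * n_resamples)),
                      1 - 1 / (2 * n_resamples))
    z0 <- stats::qnorm(prop_below)
    a <- (1 - conf) / 2
    lo_p <- stats::pnorm(2 * z0 + stats::qnorm(a))
    hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
    qs <- stats::quantile(stats, probs = c(lo_p, hi_p), names = FALSE,
                          type = 6)
    lo <- qs[1L]; hi <- qs[2L]
  }
  list(estimate = est, lower = lo, upper = hi,
       n_resamples = n_resamples, n_retried = retried)
}

#' Sensitivity, specificity and PPV at risk thresholds
#'
#' Records with predicted risk at or above the threshold are classified
#' positive (ties count as positive, matching "risk of at least t").
#'
#' @param ps a [prediction_set()].
#' @param thresholds thresholds strictly inside (0, 1).
#' @return data.frame with one row per threshold: `threshold`, `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `ppv`.
#' @export
threshold_classification <- function(ps, thresholds) {
  ps <- .as_ps(ps)
  if (any(thresholds < 0) || any(thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  rows <- lapply(thresholds, function(t) {
    pos <- ps$predicted >= t
    tp <- sum(pos & ps$observed == 1)
    fp <- sum(pos & ps$observed == 0)
    fn <- sum(!pos & ps$observed == 1)
    tn <- sum(!pos & ps$observed == 0)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Decision-curve net benefit
#'
#' Net benefit of classifying at threshold t:
#' \deqn{NB(t) = TP/n - (FP/n) \cdot t/(1-t)}
#' with the treat-all curve (everyone classified positive) and treat-none
#' (zero) as references.
#'
#' @param ps a [prediction_set()].
#' @param thresholds thresholds strictly inside (0, 1); 1 is rejected (the
#'   threshold odds are undefined).
#' @return data.frame of class `net_benefit_curve` with columns `threshold`,
#'   `net_benefit`, `treat_all`, `treat_none`.
#' @export
net_benefit <- function(ps, thresholds) {
  ps <- .as_ps(ps)
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- nrow(ps)
  prev <- mean(ps$observed)
  rows <- lapply(thresholds, function(t) {
    pos <- ps$predicted >= t
    tp <- sum(pos & ps$observed == 1)
    fp <- sum(pos & ps$observed == 0)
    odds <- t / (1 - t)
    data.frame(threshold = t,
               net_benefit = tp / n - (fp / n) * odds,
               treat_all = prev - (1 - prev) * odds,
               treat_none = 0)
  })
  structure(do.call(rbind, rows),
            class = c("net_benefit_curve", "data.frame"))
}

#' Odds ratio from a 2x2 table with Woolf interval
#'
#' For exposed cases/non-cases `a`/`b` and unexposed `c`/`d`, the odds
#' ratio is `(a/b) / (c/d)` with the Woolf (log-scale normal) 95\% CI
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell the
#' point estimate is still returned (possibly 0 or Inf) but flagged, and
#' the CI is withheld.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf confidence level.
#' @return list with `or`, `lower`, `upper`, `zero_cell`.
#' @examples
#' odds_ratio_from_counts(31, 249, 116, 12107) # ~12.99 (8.57-19.69)
#' @export
odds_ratio_from_counts <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  or <- (a / b) / (c / d)
  if (any(cells == 0)) {
    return(list(or = or, lower = NA_real_, upper = NA_real_,
                zero_cell = TRUE))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       zero_cell = FALSE)
}

#' Full validation report
#'
#' Assembles the standard model-validation summary: Brier score and AUC with
#' bias-corrected bootstrap intervals, the Spiegelhalter calibration test,
#' mean predicted vs observed probability, calibration-error percentiles,
#' and per-threshold operating characteristics.
#'
#' @param ps a [prediction_set()].
#' @param thresholds risk thresholds for the classification table.
#' @param n_resamples bootstrap resamples for the CIs.
#' @param seed integer seed for the bootstrap.
#' @return list of class `validation_report`.
#' @export
validation_report <- function(ps, thresholds = c(0.008, 0.010, 0.015),
                              n_resamples = 1000, seed = 1) {
  ps <- .as_ps(ps)
  br <- bootstrap_ci(brier, ps, n_resamples, seed)
  au <- bootstrap_ci(auc, ps, n_resamples, seed + 1)
  sp <- spiegelhalter(ps)
  cal <- tryCatch(calibration_error_percentiles(ps),
                  error = function(e) c(`50%` = NA_real_, `90%` = NA_real_))
  structure(list(n = nrow(ps),
                 events = sum(ps$observed),
                 brier = br,
                 auc = au,
                 spiegelhalter = sp,
                 mean_predicted = mean(ps$predicted),
                 mean_observed = mean(ps$observed),
                 abs_error_percentiles = cal,
                 classification = threshold_classification(ps, thresholds)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model validation report\n")
  cat(sprintf("  n = %d, events = %d (%.2f%%)\n", x$n, x$events,
              100 * x$events / x$n))
  cat(sprintf("  Brier score: %.4f (95%% CI %.4f-%.4f)\n",
              x$brier$estimate, x$brier$lower, x$brier$upper))
  cat(sprintf("  ROC AUC:     %.3f (95%% CI %.3f-%.3f)\n",
              x$auc$estimate, x$auc$lower, x$auc$upper))
  cat(sprintf("  Spiegelhalter z = %.2f, p = %.2f\n",
              x$spiegelhalter$z, x$spiegelhalter$p))
  cat(sprintf("  mean predicted / observed: %.4f / %.4f\n",
              x$mean_predicted, x$mean_observed))
  if (!anyNA(x$abs_error_percentiles)) {
    cat(sprintf("  50th, 90th percentile absolute error: %.4f, %.4f\n",
                x$abs_error_percentiles[1], x$abs_error_percentiles[2]))
  }
  cat("  operating characteristics:\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}
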