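# Core risk engine: Lung-RADS dichotomization, screening-history grouping,
# the results-adjusted risk prediction, and the ceiling-probability solver.

# Pattern order follows the 8-level table: index 1 = (- - -), then by T0/T1/T2.
.pattern_labels <- c("---", "+--", "-+-", "++-", "--+", "+-+", "-++", "+++")
.pattern_group <- c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L)

#' Dichotomize Lung-RADS categories
#'
#' Lung-RADS 1 and 2 do not trigger further workup and are negative;
#' Lung-RADS 3, 4A, 4B and 4X are positive. Parsing is case-insensitive,
#' accepts a bare `"4"`, and passes through already-dichotomized values
#' (`"+"/"-"`, `"positive"/"negative"`, `"pos"/"neg"`).
#'
#' @param x vector of Lung-RADS categories (character or numeric 1-4).
#' @return factor with levels `negative`, `positive`.
#' @examples
#' lungrads_dichotomize(c("1", "2", "3", "4A", "4B", "4X"))
#' @export
lungrads_dichotomize <- function(x) {
  v <- toupper(trimws(as.character(x)))
  neg <- c("1", "2", "-", "NEG", "NEGATIVE")
  pos <- c("3", "4", "4A", "4B", "4X", "+", "POS", "POSITIVE")
  out <- rep(NA_character_, length(v))
  out[v %in% neg] <- "negative"
  out[v %in% pos] <- "positive"
  if (anyNA(out)) {
    bad <- unique(v[is.na(out)])
    stop("unknown Lung-RADS category: ", paste(bad, collapse = ", "),
         " (expected 1, 2, 3, 4, 4A, 4B, 4X or +/-)", call. = FALSE)
  }
  factor(out, levels = c("negative", "positive"))
}

.as_positive <- function(x, screen = "screen") {
  if (anyNA(x)) {
    stop("missing ", screen,
         " result: complete three-screen histories are required", call. = FALSE)
  }
  if (is.logical(x)) return(x)
  lungrads_dichotomize(x) == "positive"
}

#' Group a three-screen history
#'
#' Maps the eight T0/T1/T2 dichotomized patterns onto the 4-level
#' screening-result groups used by the results-adjusted model:
#' group 1 all negative `(- - -)`; group 2 one positive with last negative
#' `(+ - -)`, `(- + -)`; group 3 two positives with last negative or last
#' screen the only positive `(+ + -)`, `(- - +)`; group 4 at least two
#' positives with the last positive `(+ - +)`, `(- + +)`, `(+ + +)`.
#'
#' @param t0,t1,t2 per-screen results: Lung-RADS categories, `"+"/"-"`, or
#'   logical (`TRUE` = positive). Vectors are processed in parallel.
#' @return data.frame with columns `pattern` (the `+/-` string),
#'   `level8` (pattern index 1-8) and `group` (1-4).
#' @examples
#' group_history("-", "-", "-")$group # 1
#' group_history("4A", "1", "3")$group # 4
#' @export
group_history <- function(t0, t1, t2) {
  p0 <- .as_positive(t0, "T0")
  p1 <- .as_positive(t1, "T1")
  p2 <- .as_positive(t2, "T2")
  n <- max(length(p0), length(p1), length(p2))
  p0 <- rep_len(p0, n); p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  # binary encoding T0 + 2*T1 + 4*T2: the natural order
  # ---,+--,-+-,++-,--+,+-+,-++,+++ coincides with the 8-level table order
  idx <- 1L + p0 + 2L * p1 + 4L * p2
  data.frame(pattern = .pattern_labels[idx],
             level8 = idx,
             group = .pattern_group[idx])
}

.eta <- function(base_risk_3yr, group, coef) {
  bg <- c(0, coef$beta_group)[group]
  tr <- if (coef$fp_power == 0) log(base_risk_3yr) else base_risk_3yr^coef$fp_power
  coef$intercept + bg + coef$beta_fp * (tr - coef$centering)
}

#' Predict post-screening lung cancer risk
#'
#' Evaluates the results-adjusted model: the 6-year base risk (PLCOm2012
#' scale) is halved to the 3-year follow-up scale, transformed by the
#' fractional-polynomial power, combined with the screening-group
#' coefficient, and passed through the logistic link. The 6-year-equivalent
#' output doubles the predicted 3-year risk (capped at 1), the inverse of
#' the halving applied on input.
#'
#' @param base_risk_6yr 6-year base model risk(s), strictly inside (0, 1).
#' @param group screening-result group 1-4, or a data.frame from
#'   [group_history()].
#' @param coef model coefficients, see [results_model_coef()].
#' @param warn_high warn when a predicted 3-year risk exceeds 12\%, the
#'   region where external validation showed overestimation.
#' @return data.frame of class `risk_estimate` with columns
#'   `base_risk_6yr`, `base_risk_3yr`, `group`, `risk_3yr`,
#'   `risk_6yr_equivalent`.
#' @examples
#' # 3% 6-year base risk, two or more positive screens with last positive:
#' predict_results_risk(0.03, 4)$risk_6yr_equivalent # ~0.15
#' @export
predict_results_risk <- function(base_risk_6yr, group,
                                 coef = results_model_coef(),
                                 warn_high = TRUE) {
  stopifnot(inherits(coef, "results_model_coef"))
  if (is.data.frame(group)) group <- group$group
  group <- as.integer(group)
  if (anyNA(base_risk_6yr) || any(base_risk_6yr <= 0) || any(base_risk_6yr >= 1)) {
    stop("base_risk_6yr must lie strictly inside (0, 1); ",
         "a base risk of 0 is undefined under the fractional-polynomial transform",
         call. = FALSE)
  }
  if (anyNA(group) || any(group < 1L) || any(group > 4L)) {
    stop("group must be an integer in 1..4", call. = FALSE)
  }
  n <- max(length(base_risk_6yr), length(group))
  base_risk_6yr <- rep_len(base_risk_6yr, n)
  group <- rep_len(group, n)
  base3 <- base_risk_6yr / 2
  p3 <- stats::plogis(.eta(base3, group, coef))
  if (warn_high && any(p3 > 0.12)) {
    warning(sum(p3 > 0.12), " prediction(s) exceed a 3-year risk of 12%, ",
            "where the model is known to overestimate", call. = FALSE)
  }
  out <- data.frame(base_risk_6yr = base_risk_6yr,
                    base_risk_3yr = base3,
                    group = group,
                    risk_3yr = p3,
                    risk_6yr_equivalent = pmin(1, 2 * p3))
  class(out) <- c("risk_estimate", "data.frame")
  out
}

#' Ceiling probability for a screening-eligibility threshold
#'
#' The minimum 6-year base risk at which three consecutive negative screens
#' cannot bring the results-adjusted 6-year-equivalent risk below the
#' eligibility threshold. People at or above the ceiling should continue
#' annual screening regardless of negative results; the published ceilings
#' are 2.6\% for a 1.5\% threshold and 3.4\% for a 2.0\% threshold.
#'
#' Solved by closed-form inversion of the logistic / fractional-polynomial
#' equation on the all-negative stratum; a bracketed root finder (relative
#' tolerance 1e-10) is the fallback for coefficient sets without an analytic
#' inverse.
#'
#' @param threshold_6yr eligibility threshold on the 6-year risk scale.
#' @inheritParams predict_results_risk
#' @return the ceiling 6-year base risk (vectorized over `threshold_6yr`).
#' @examples
#' ceiling_probability(0.015) # ~0.026
#' ceiling_probability(0.020) # ~0.034
#' @export
ceiling_probability <- function(threshold_6yr, coef = results_model_coef()) {
  stopifnot(inherits(coef, "results_model_coef"))
  if (anyNA(threshold_6yr) || any(threshold_6yr <= 0) || any(threshold_6yr >= 1)) {
    stop("threshold_6yr must lie strictly inside (0, 1)", call. = FALSE)
  }
  vapply(threshold_6yr, .ceiling_one, numeric(1), coef = coef)
}

.ceiling_one <- function(threshold, coef) {
  target_eta <- stats::qlogis(threshold / 2) # model output on the 3-yr scale
  # invert eta = b0 + beta_fp * (p3^power - centering) on the all-negative stratum
  tr <- (target_eta - coef$intercept) / coef$beta_fp + coef$centering
  p6 <- NA_real_
  if (coef$fp_power == 0) {
    p6 <- 2 * exp(tr)
  } else if (tr > 0) {
    p6 <- 2 * tr^(1 / coef$fp_power)
  }
  if (!is.na(p6) && p6 > 0 && p6 < 1) {
    return(p6)
  }
  # analytic inverse fell outside the domain: bracketed root finding
  f <- function(p) {
    predict_results_risk(p, 1L, coef, warn_high = FALSE)$risk_6yr_equivalent -
      threshold
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  if (f(hi) < 0 || f(lo) > 0) {
    stop(sprintf(paste0("threshold %.4g is not reachable by any base risk in ",
                        "(0, 1) on the all-negative stratum"), threshold),
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Screening-interval decision rule
#'
#' Applies the decision logic for offering the next annual screen: anyone
#' with a positive screen continues annual screening; among the all-negative,
#' those whose base risk reaches the ceiling probability for the chosen
#' eligibility threshold continue, and the rest may consider omitting the
#' next annual screen (with annual risk reassessment).
#'
#' @inheritParams predict_results_risk
#' @param t0,t1,t2 per-screen results as in [group_history()].
#' @param threshold_6yr screening-eligibility threshold on the 6-year scale.
#' @return factor with levels `continue_annual`, `consider_omit_next`.
#' @examples
#' eligibility_decision(0.03, "-", "-", "-", threshold_6yr = 0.015)
#' @export
eligibility_decision <- function(base_risk_6yr, t0, t1, t2,
                                 threshold_6yr = 0.015,
                                 coef = results_model_coef()) {
  h <- group_history(t0, t1, t2)
  # validate base risks through the predictor's contract
  predict_results_risk(base_risk_6yr, h$group, coef, warn_high = FALSE)
  ceil <- ceiling_probability(threshold_6yr, coef)
  n <- max(length(base_risk_6yr), nrow(h))
  base_risk_6yr <- rep_len(base_risk_6yr, n)
  keep <- h$group > 1L | base_risk_6yr >= ceil
  factor(ifelse(keep, "continue_annual", "consider_omit_next"),
         levels = c("continue_annual", "consider_omit_next"))
}
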