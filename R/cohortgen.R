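# Synthetic NLST-like cohort generator. Emulates the marginal structure the
# results-adjusted model assumes — base-risk distribution, screening-result
# group frequencies, and outcomes drawn from the model itself — so fitting,
# validation and decision modules are testable without any trial data.

#' Configuration of the synthetic cohort
#'
#' Defaults state the emulated world once:
#' \itemize{
#'   \item base 6-year risk is log-normal with median 1.5\% (the common
#'     screening-eligibility threshold) and `sdlog` 0.8, truncated to
#'     (0.001, 0.30) by resampling;
#'   \item screening-result groups 1-4 are drawn with the development-set
#'     frequencies 80.7 / 13.4 / 4.1 / 1.8 \%;
#'   \item within groups, 8-level patterns follow the development-set
#'     proportions (group 2 `+--`:`-+-` = 1565:463; group 3 `++-`:`--+`
#'     = 125:496; group 4 `+-+`:`-++`:`+++` = 147:91:42);
#'   \item the binary 3-year lung-cancer outcome is Bernoulli with
#'     probability given by [predict_results_risk()] — calibrated by
#'     construction;
#'   \item competing (non-lung-cancer) death has constant hazard
#'     0.0112 / year, giving roughly 735 deaths per 22 229 people over the
#'     3-year window.
#' }
#'
#' @param n cohort size.
#' @param base_risk_meanlog,base_risk_sdlog log-normal parameters of the
#'   6-year base risk.
#' @param base_risk_range truncation bounds (open interval, by resampling).
#' @param group_probs frequencies of screening groups 1-4; must sum to 1.
#' @param pattern_weights within-group 8-level pattern weights.
#' @param competing_death_rate constant yearly hazard of competing death.
#' @param horizon follow-up truncation in years.
#' @param coef the generating model, a [results_model_coef()].
#' @param group_risk_cor optional dependence knob: a non-negative number
#'   `k` makes the group-assignment odds of the higher groups scale with
#'   `(base risk / median)^k`; 0 (default) samples groups independently of
#'   base risk.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n = 10000,
                          base_risk_meanlog = log(0.015),
                          base_risk_sdlog = 0.8,
                          base_risk_range = c(0.001, 0.30),
                          group_probs = c(0.807, 0.134, 0.041, 0.018),
                          pattern_weights = list(g1 = 1,
                                                 g2 = c(1565, 463),
                                                 g3 = c(125, 496),
                                                 g4 = c(147, 91, 42)),
                          competing_death_rate = 0.0112,
                          horizon = 3,
                          coef = results_model_coef(),
                          group_risk_cor = 0) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (length(group_probs) != 4L || any(group_probs < 0) ||
      abs(sum(group_probs) - 1) > 1e-6) {
    stop("group_probs must be 4 non-negative frequencies summing to 1",
         call. = FALSE)
  }
  stopifnot(inherits(coef, "results_model_coef"),
            competing_death_rate >= 0, horizon > 0, group_risk_cor >= 0)
  structure(list(n = as.integer(n),
                 base_risk_meanlog = base_risk_meanlog,
                 base_risk_sdlog = base_risk_sdlog,
                 base_risk_range = base_risk_range,
                 group_probs = group_probs / sum(group_probs),
                 pattern_weights = pattern_weights,
                 competing_death_rate = competing_death_rate,
                 horizon = horizon,
                 coef = coef,
                 group_risk_cor = group_risk_cor),
            class = "cohort_config")
}

.sample_truncated_lognormal <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, draw[draw > range[1] & draw < range[2]])
  }
  out[seq_len(n)]
}

# 8-level patterns by group, indices into the pattern table
.group_patterns <- list(`1` = 1L, `2` = c(2L, 3L), `3` = c(4L, 5L),
                        `4` = c(6L, 7L, 8L))

#' Sample 8-level patterns within a screening group
#'
#' @param group vector of groups 1-4.
#' @param config a [cohort_config()] (for the pattern weights).
#' @return integer vector of 8-level pattern indices.
#' @export
pattern_within_group <- function(group, config = cohort_config()) {
  group <- as.integer(group)
  if (any(group < 1L | group > 4L)) stop("group must be 1..4", call. = FALSE)
  w <- config$pattern_weights
  out <- integer(length(group))
  for (g in 1:4) {
    i <- which(group == g)
    if (!length(i)) next
    pats <- .group_patterns[[g]]
    out[i] <- if (length(pats) == 1L) pats else
      sample(pats, length(i), replace = TRUE,
             prob = w[[g]] / sum(w[[g]]))
  }
  out
}

#' Generate a synthetic screening cohort
#'
#' Draws base risks, screening histories, binary 3-year outcomes from the
#' generating model, and a competing-risks survival view of the same
#' follow-up (lung-cancer events get a uniform event time in the window;
#' competing death is exponential; the earlier one is observed, and
#' survivors are censored administratively at the horizon).
#'
#' The binary `outcome` column is the logistic-model target (it ignores the
#' competing-death preemption, matching the complete-follow-up contract of
#' the development design); `time`/`event_type` are the survival view in
#' which a death can preempt the cancer.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; required for reproducibility.
#' @return data.frame with columns `id`, `plco6`, `s0`, `s1`, `s2`
#'   (`"+"/"-"`), `pattern`, `level8`, `group`, `risk_3yr`, `outcome`,
#'   `time`, `event_type` (0 censored / 1 lung cancer / 2 competing death).
#' @examples
#' head(generate_cohort(cohort_config(n = 100), seed = 1))
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  n <- config$n
  plco6 <- .sample_truncated_lognormal(n, config$base_risk_meanlog,
                                       config$base_risk_sdlog,
                                       config$base_risk_range)
  if (config$group_risk_cor > 0) {
    # tilt group odds with base risk relative to the distribution median
    rel <- (plco6 / exp(config$base_risk_meanlog))^config$group_risk_cor
    group <- vapply(rel, function(r) {
      w <- config$group_probs * c(1, r, r, r)
      sample.int(4L, 1L, prob = w / sum(w))
    }, integer(1))
  } else {
    group <- sample.int(4L, n, replace = TRUE, prob = config$group_probs)
  }
  level8 <- pattern_within_group(group, config)
  pattern <- .pattern_labels[level8]
  risk <- predict_results_risk(plco6, group, config$coef, warn_high = FALSE)
  outcome <- stats::rbinom(n, 1L, risk$risk_3yr)

  cancer_time <- ifelse(outcome == 1L, stats::runif(n, 0, config$horizon), Inf)
  death_time <- if (config$competing_death_rate > 0) {
    stats::rexp(n, config$competing_death_rate)
  } else rep(Inf, n)
  time <- pmin(cancer_time, death_time, config$horizon)
  event_type <- ifelse(cancer_time <= pmin(death_time, config$horizon), 1L,
                       ifelse(death_time <= config$horizon, 2L, 0L))

  sgn <- function(k) substr(pattern, k, k)
  data.frame(id = seq_len(n),
             plco6 = plco6,
             s0 = ifelse(sgn(1) == "+", "+", "-"),
             s1 = ifelse(sgn(2) == "+", "+", "-"),
             s2 = ifelse(sgn(3) == "+", "+", "-"),
             pattern = pattern,
             level8 = level8,
             group = group,
             risk_3yr = risk$risk_3yr,
             outcome = outcome,
             time = time,
             event_type = event_type,
             stringsAsFactors = FALSE)
}

#' Analytic expected event fraction of a cohort configuration
#'
#' Numerically integrates the generating model's 3-year risk over the
#' truncated log-normal base-risk distribution, mixed over the group
#' frequencies. Used as the oracle against which simulated event fractions
#' are checked (only valid for `group_risk_cor = 0`).
#'
#' @param config a [cohort_config()].
#' @return the expected fraction of lung-cancer outcomes.
#' @export
expected_event_fraction <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$group_risk_cor != 0) {
    stop("analytic expectation is only available for independent group ",
         "assignment (group_risk_cor = 0)", call. = FALSE)
  }
  r <- config$base_risk_range
  norm <- stats::plnorm(r[2], config$base_risk_meanlog, config$base_risk_sdlog) -
    stats::plnorm(r[1], config$base_risk_meanlog, config$base_risk_sdlog)
  per_group <- vapply(1:4, function(g) {
    stats::integrate(function(p) {
      d <- stats::dlnorm(p, config$base_risk_meanlog, config$base_risk_sdlog) / norm
      predict_results_risk(p, g, config$coef, warn_high = FALSE)$risk_3yr * d
    }, lower = r[1], upper = r[2], rel.tol = 1e-9)$value
  }, numeric(1))
  sum(config$group_probs * per_group)
}
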