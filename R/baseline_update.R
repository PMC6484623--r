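# Baseline updating of risk-model covariates to the start of follow-up, the
# 6-year -> 3-year risk-scale conversion, and evaluation of a pluggable
# logistic base-risk model from a coefficient config.

#' Baseline covariates for a base risk model
#'
#' Holds the covariates a base lung-cancer risk model needs. Age, smoking
#' duration and quit time are explicit because they are the fields that get
#' advanced in time by [update_to_t3()]; any other covariates the base model
#' uses are carried opaquely in `...` as named values.
#'
#' @param age age in years. Values outside the usual 50-85 screening range
#'   are flagged with a warning, not rejected.
#' @param smoking_status `"current"` or `"former"`.
#' @param smoking_duration years smoked, non-negative.
#' @param quit_time years since quitting; required for former smokers and
#'   disallowed for current smokers.
#' @param ... further named covariates, passed through untouched.
#' @return object of class `baseline_covariates` (a named list).
#' @export
baseline_covariates <- function(age, smoking_status, smoking_duration,
                                quit_time = NULL, ...) {
  smoking_status <- match.arg(smoking_status, c("current", "former"))
  stopifnot(is.numeric(age), length(age) == 1L,
            is.numeric(smoking_duration), length(smoking_duration) == 1L)
  if (smoking_duration < 0) stop("smoking_duration must be >= 0", call. = FALSE)
  if (smoking_status == "former") {
    if (is.null(quit_time)) {
      stop("quit_time is required for former smokers", call. = FALSE)
    }
    if (quit_time < 0) stop("quit_time must be >= 0", call. = FALSE)
  } else if (!is.null(quit_time)) {
    stop("quit_time must be absent for current smokers", call. = FALSE)
  }
  if (age < 50 || age > 85) {
    warning("age ", age, " is outside the usual 50-85 screening range",
            call. = FALSE)
  }
  structure(c(list(age = age, smoking_status = smoking_status,
                   smoking_duration = smoking_duration,
                   quit_time = quit_time), list(...)),
            class = "baseline_covariates")
}

#' Advance covariates from study baseline to the start of follow-up
#'
#' Time-dependent covariates measured at the baseline screen are advanced to
#' the start of the post-screening follow-up window (T3, three years after
#' baseline): age increases by the elapsed time; smoking duration increases
#' for current smokers; quit time increases for former smokers. Changes in
#' smoking status between baseline and T3 are deliberately not modelled.
#'
#' @param covariates a [baseline_covariates()] object.
#' @param elapsed years elapsed since baseline (default 3).
#' @return the updated `baseline_covariates`.
#' @examples
#' update_to_t3(baseline_covariates(61, "current", 40))
#' @export
update_to_t3 <- function(covariates, elapsed = 3) {
  stopifnot(inherits(covariates, "baseline_covariates"))
  if (!is.numeric(elapsed) || length(elapsed) != 1L || elapsed < 0) {
    stop("elapsed must be a single non-negative number of years", call. = FALSE)
  }
  covariates$age <- covariates$age + elapsed
  if (covariates$smoking_status == "current") {
    covariates$smoking_duration <- covariates$smoking_duration + elapsed
  } else {
    covariates$quit_time <- covariates$quit_time + elapsed
  }
  covariates
}

#' Convert a 6-year risk to the 3-year follow-up scale
#'
#' The simple halving used when the follow-up window is half the base
#' model's horizon. The halving (rather than `1 - (1 - p)^0.5`) is kept
#' deliberately: the downstream fitted coefficients assume it.
#'
#' @param risk6 6-year risk(s) in \[0, 1\].
#' @return `risk6 / 2`.
#' @export
six_to_three_year <- function(risk6) {
  if (anyNA(risk6) || any(risk6 < 0) || any(risk6 > 1)) {
    stop("risk6 must lie in [0, 1]", call. = FALSE)
  }
  risk6 / 2
}

#' Specify a pluggable logistic base-risk model
#'
#' A declarative description of a logistic risk model (such as PLCOm2012,
#' whose coefficients are distributed separately) that can be evaluated on
#' [baseline_covariates()]. Each term names a covariate, a transform from a
#' small vocabulary, and a coefficient:
#' \describe{
#'   \item{identity}{use the value as is}
#'   \item{power}{raise to `power` (0 means natural log)}
#'   \item{indicator}{1 if the value equals `level`, else 0}
#' }
#' Every transform may subtract a `center` after transformation.
#'
#' @param intercept model constant.
#' @param terms a list of terms, each a list with elements `covariate`,
#'   `transform`, `coefficient` and optionally `power`, `level`, `center`.
#' @return object of class `base_model_spec`.
#' @examples
#' spec <- base_model_spec(-6, list(
#'   list(covariate = "age", transform = "identity",
#'        coefficient = 0.08, center = 62),
#'   list(covariate = "smoking_status", transform = "indicator",
#'        level = "current", coefficient = 0.5)))
#' @export
base_model_spec <- function(intercept, terms) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.list(terms))
  terms <- lapply(terms, function(tm) {
    if (is.null(tm$covariate) || is.null(tm$transform) || is.null(tm$coefficient)) {
      stop("each term needs covariate, transform and coefficient", call. = FALSE)
    }
    tm$transform <- match.arg(tm$transform, c("identity", "power", "indicator"))
    if (tm$transform == "power" && is.null(tm$power)) {
      stop("power transform on ", tm$covariate, " needs a `power`", call. = FALSE)
    }
    if (tm$transform == "indicator" && is.null(tm$level)) {
      stop("indicator transform on ", tm$covariate, " needs a `level`",
           call. = FALSE)
    }
    if (is.null(tm$center)) tm$center <- 0
    tm
  })
  structure(list(intercept = intercept, terms = terms),
            class = "base_model_spec")
}

#' Evaluate a base-risk model on one person's covariates
#'
#' @param covariates a [baseline_covariates()] object (or plain named list).
#' @param spec a [base_model_spec()].
#' @return predicted probability (logistic of the linear predictor).
#' @export
evaluate_base_model <- function(covariates, spec) {
  stopifnot(inherits(spec, "base_model_spec"))
  lp <- spec$intercept
  for (tm in spec$terms) {
    if (is.null(covariates[[tm$covariate]])) {
      stop("covariate required by the base model is missing: ", tm$covariate,
           call. = FALSE)
    }
    v <- covariates[[tm$covariate]]
    x <- switch(tm$transform,
                identity = as.numeric(v),
                power = if (tm$power == 0) log(as.numeric(v)) else as.numeric(v)^tm$power,
                indicator = as.numeric(v == tm$level))
    lp <- lp + tm$coefficient * (x - tm$center)
  }
  stats::plogis(lp)
}

#' Read a base-model specification from JSON
#'
#' The file schema mirrors [base_model_spec()]: a top-level `intercept` and
#' a `terms` array. A synthetic demonstration file ships at
#' `system.file("extdata", "base_model_synthetic.json", package = "lungscreenrisk")`.
#'
#' @param path file path.
#' @return a `base_model_spec`.
#' @export
read_base_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$intercept) || is.null(x$terms)) {
    stop("base model file ", path, " must have `intercept` and `terms`",
         call. = FALSE)
  }
  base_model_spec(x$intercept, x$terms)
}
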