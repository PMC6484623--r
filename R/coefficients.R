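#' PLCO2012results model coefficients
#'
#' Container for the fitted coefficients of the results-adjusted risk model:
#' a logistic regression on the fractional-polynomial transformed 3-year base
#' risk plus indicator terms for the 4-level screening-result group. The
#' defaults are the published PLCO2012results estimates fitted in the NLST
#' LSS development set; alternative fitted models (e.g. from
#' [select_fp()]) plug in through the same structure.
#'
#' The linear predictor for a person with 3-year base risk \eqn{p} in
#' screening group \eqn{g} is
#' \deqn{\eta = \beta_0 + \beta_g + \beta_{fp} (p^{power} - centering)}
#' with \eqn{\beta_1 = 0} (all-negative reference group), and the predicted
#' 3-year risk is \eqn{logit^{-1}(\eta)}.
#'
#' @param intercept model constant.
#' @param beta_group named numeric vector of log odds ratios for screening
#'   groups 2-4 relative to the all-negative group; names must be
#'   `group2`, `group3`, `group4`.
#' @param beta_fp coefficient of the transformed base risk.
#' @param fp_power fractional-polynomial power applied to the 3-year base
#'   risk (`0` means natural log).
#' @param centering constant subtracted from the transformed base risk
#'   (a development-dataset constant; it only shifts the intercept).
#' @return An object of class `results_model_coef`.
#' @examples
#' coef <- results_model_coef()
#' exp(coef$beta_group["group4"]) # multivariable OR for group 4, ~8.97
#' @export
results_model_coef <- function(intercept = -4.4353800,
                               beta_group = c(group2 = 0.6554117,
                                              group3 = 0.9798233,
                                              group4 = 2.1940610),
                               beta_fp = -0.2713125,
                               fp_power = -0.5,
                               centering = 7.045149954) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(beta_fp), length(beta_fp) == 1L,
            is.numeric(fp_power), length(fp_power) == 1L,
            is.numeric(centering), length(centering) == 1L)
  if (!is.numeric(beta_group) || length(beta_group) != 3L ||
      !identical(sort(names(beta_group)), c("group2", "group3", "group4"))) {
    stop("`beta_group` must be a numeric vector with names group2, group3, group4",
         call. = FALSE)
  }
  structure(list(intercept = intercept,
                 beta_group = beta_group[c("group2", "group3", "group4")],
                 beta_fp = beta_fp,
                 fp_power = fp_power,
                 centering = centering),
            class = "results_model_coef")
}

#' @export
print.results_model_coef <- function(x, ...) {
  cat("Results-adjusted lung cancer risk model coefficients\n")
  cat(sprintf("  intercept:  %.7f\n", x$intercept))
  cat(sprintf("  group 2:    %.7f  (OR %.2f)\n", x$beta_group[["group2"]],
              exp(x$beta_group[["group2"]])))
  cat(sprintf("  group 3:    %.7f  (OR %.2f)\n", x$beta_group[["group3"]],
              exp(x$beta_group[["group3"]])))
  cat(sprintf("  group 4:    %.7f  (OR %.2f)\n", x$beta_group[["group4"]],
              exp(x$beta_group[["group4"]])))
  cat(sprintf("  base risk:  %.7f on (3-yr risk)^%g, centered at %.9f\n",
              x$beta_fp, x$fp_power, x$centering))
  invisible(x)
}

#' Read or write model coefficients as JSON
#'
#' Coefficients are data, not code: they are shipped and exchanged as a
#' human-readable JSON file so refitted models are pluggable. The schema has
#' keys `intercept`, `beta_group` (object with `group2`..`group4`),
#' `beta_fp`, `fp_power`, `centering`.
#'
#' @param path file path.
#' @return `read_model_coef()` returns a `results_model_coef`;
#'   `write_model_coef()` returns `path` invisibly.
#' @export
read_model_coef <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("intercept", "beta_group", "beta_fp", "fp_power", "centering")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("coefficient file ", path, " is missing keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  results_model_coef(intercept = x$intercept,
                     beta_group = unlist(x$beta_group),
                     beta_fp = x$beta_fp,
                     fp_power = x$fp_power,
                     centering = x$centering)
}

#' @param coef a `results_model_coef` object.
#' @rdname read_model_coef
#' @export
write_model_coef <- function(coef, path) {
  stopifnot(inherits(coef, "results_model_coef"))
  jsonlite::write_json(list(intercept = coef$intercept,
                            beta_group = as.list(coef$beta_group),
                            beta_fp = coef$beta_fp,
                            fp_power = coef$fp_power,
                            centering = coef$centering),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
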