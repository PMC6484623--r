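# Logistic model fitting with fractional-polynomial power selection for a
# single continuous predictor, as used to develop the results-adjusted model.

#' Candidate fractional-polynomial powers
#'
#' The conventional candidate set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, with 0
#' meaning the natural log.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Apply a fractional-polynomial transform
#'
#' @param x strictly positive numeric vector.
#' @param power a power from the candidate set; 0 means log.
#' @return transformed vector.
#' @export
fp_transform <- function(x, power) {
  if (any(x <= 0)) {
    stop("fractional-polynomial transforms require strictly positive values; ",
         "no origin shift is applied silently", call. = FALSE)
  }
  if (power == 0) log(x) else x^power
}

#' Fitting configuration
#'
#' @param degree maximum fractional-polynomial degree, 1 (default, a single
#'   power — what the published model uses) or 2.
#' @param alpha significance level of the closed-test selection sequence.
#' @param tol IRLS convergence tolerance on the relative deviance change.
#' @param maxit maximum IRLS iterations.
#' @param centering `"mean"` centers the transformed predictor at its sample
#'   mean (a dataset constant absorbed by the intercept); `"none"` skips it.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(degree = 1, alpha = 0.05, tol = 1e-8, maxit = 100,
                       centering = c("mean", "none")) {
  stopifnot(degree %in% c(1, 2), alpha > 0, alpha < 1, tol > 0, maxit >= 1)
  structure(list(degree = degree, alpha = alpha, tol = tol, maxit = maxit,
                 centering = match.arg(centering)),
            class = "fit_config")
}

#' Maximum-likelihood logistic regression
#'
#' Fits by iteratively reweighted least squares (via `stats::glm.fit`) and
#' fails loudly on non-convergence or separation instead of returning
#' unusable estimates.
#'
#' @param design numeric matrix of predictors. An intercept column of ones
#'   is prepended unless one is already present.
#' @param outcome binary 0/1 vector.
#' @param config a [fit_config()].
#' @return list with `coefficients`, `se`, `vcov`, `deviance`,
#'   `null_deviance`, `fitted`, `converged`.
#' @examples
#' x <- cbind(exposed = rep(c(1, 0), c(10, 10)))
#' y <- rep(c(1, 0, 1, 0), c(6, 4, 2, 8))
#' fit_logistic(x, y)$coefficients
#' @export
fit_logistic <- function(design, outcome, config = fit_config()) {
  design <- as.matrix(design)
  if (!is.numeric(design)) stop("design must be numeric", call. = FALSE)
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (nrow(design) != length(outcome)) {
    stop("design and outcome lengths differ", call. = FALSE)
  }
  has_intercept <- any(apply(design, 2, function(c) all(c == 1)))
  if (!has_intercept) {
    design <- cbind(`(Intercept)` = 1, design)
  }
  constant <- apply(design, 2, function(c) length(unique(c)) == 1L & !all(c == 1))
  if (any(constant)) {
    stop("constant non-intercept column(s) in design: ",
         paste(colnames(design)[constant], collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(design, outcome, family = stats::binomial(),
                   control = stats::glm.control(epsilon = config$tol,
                                                maxit = config$maxit))
  )
  if (!fit$converged) {
    stop("logistic fit failed: IRLS did not converge in ", config$maxit,
         " iterations", call. = FALSE)
  }
  if (any(outcome == 1) && any(outcome == 0) && fit$rank > 1) {
    # perfect separation: every case outranks every control, with the
    # linear predictor running off to the boundary
    if (min(fit$fitted.values[outcome == 1]) >
          max(fit$fitted.values[outcome == 0]) &&
        max(abs(fit$linear.predictors)) > 15) {
      stop("logistic fit failed: the design separates the outcome ",
           "(no finite maximum-likelihood estimate)", call. = FALSE)
    }
  }
  w <- fit$weights
  xtx <- crossprod(design * sqrt(w))
  vc <- tryCatch(solve(xtx), error = function(e) {
    stop("logistic fit failed: singular information matrix", call. = FALSE)
  })
  dimnames(vc) <- list(colnames(design), colnames(design))
  list(coefficients = stats::setNames(fit$coefficients, colnames(design)),
       se = sqrt(diag(vc)),
       vcov = vc,
       deviance = fit$deviance,
       null_deviance = fit$null.deviance,
       fitted = fit$fitted.values,
       converged = fit$converged)
}

.fp_design <- function(x, powers) {
  cols <- lapply(seq_along(powers), function(i) {
    v <- fp_transform(x, powers[i])
    # repeated power in degree-2 FP: second column is x^p * log(x)
    if (i > 1 && powers[i] == powers[i - 1]) v <- v * log(x)
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("fp", seq_along(powers))
  m
}

.fp_candidates <- function(degree) {
  if (degree == 1) {
    lapply(fp_powers(), function(p) p)
  } else {
    pw <- fp_powers()
    out <- list()
    for (i in seq_along(pw)) for (j in i:length(pw)) {
      out[[length(out) + 1L]] <- c(pw[i], pw[j])
    }
    out
  }
}

#' Select a fractional-polynomial transform by the closed test
#'
#' Fits the logistic model with the continuous predictor transformed by each
#' candidate power (and, for degree 2, each pair of powers), then applies
#' the closed-test sequence at level `alpha`: (1) best FP vs the model
#' omitting the predictor (2 df per FP degree) — if not significant the
#' predictor is dropped; (2) best FP vs the linear (power 1) model — if not
#' significant the linear model is kept; otherwise the best-deviance FP is
#' selected. Deviance ties break toward the simpler (linear) model.
#'
#' @param x strictly positive continuous predictor.
#' @param outcome binary 0/1 vector.
#' @param covariates optional numeric matrix of additional (e.g. group
#'   indicator) columns kept in every model.
#' @param config a [fit_config()].
#' @return object of class `fp_fit`: `powers` (selected, `NULL` if the
#'   predictor was dropped, `1` for linear), `coefficients`, `se`,
#'   `deviance`, `centering` (per transformed column), `closed_test`
#'   (the deviances and p-values of the selection sequence), and
#'   `as_model_coef()`-ready pieces when the design matches the
#'   screening-group layout.
#' @export
select_fp <- function(x, outcome, covariates = NULL, config = fit_config()) {
  if (any(x <= 0)) {
    stop("continuous predictor must be strictly positive for ",
         "fractional-polynomial powers", call. = FALSE)
  }
  base_design <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(outcome), ncol = 0)
  } else {
    as.matrix(covariates)
  }

  fit_with <- function(extra) {
    fit_logistic(cbind(base_design, extra), outcome, config)
  }

  null_fit <- fit_with(NULL)
  lin_fit <- fit_with(cbind(fp1 = x))

  cands <- .fp_candidates(config$degree)
  fits <- lapply(cands, function(p) fit_with(.fp_design(x, p)))
  devs <- vapply(fits, `[[`, numeric(1), "deviance")
  best <- which.min(devs)
  # tie toward the simpler linear model
  lin_idx <- which(vapply(cands, function(p) identical(p, 1), logical(1)))
  if (length(lin_idx) && devs[lin_idx] <= min(devs) + 1e-12) best <- lin_idx

  df_fp <- 2 * config$degree
  p_null <- stats::pchisq(null_fit$deviance - devs[best], df = df_fp,
                          lower.tail = FALSE)
  p_lin <- stats::pchisq(lin_fit$deviance - devs[best], df = df_fp - 1,
                         lower.tail = FALSE)

  if (p_null >= config$alpha) {
    selected <- NULL; sel_fit <- null_fit
  } else if (p_lin >= config$alpha) {
    selected <- 1; sel_fit <- lin_fit
  } else {
    selected <- cands[[best]]; sel_fit <- fits[[best]]
  }

  centering <- 0
  if (!is.null(selected) && config$centering == "mean") {
    # centering shifts only the intercept; recompute rather than refit
    tr <- .fp_design(x, selected)
    centering <- colMeans(tr)
    k <- ncol(base_design) + 1L # intercept added by fit_logistic
    fp_cols <- seq.int(k + 1L, length(sel_fit$coefficients))
    sel_fit$coefficients[1L] <- sel_fit$coefficients[1L] +
      sum(sel_fit$coefficients[fp_cols] * centering)
  }

  structure(list(powers = selected,
                 coefficients = sel_fit$coefficients,
                 se = sel_fit$se,
                 vcov = sel_fit$vcov,
                 deviance = sel_fit$deviance,
                 centering = centering,
                 closed_test = list(dev_null = null_fit$deviance,
                                    dev_linear = lin_fit$deviance,
                                    dev_best = devs[best],
                                    best_powers = cands[[best]],
                                    p_vs_null = p_null,
                                    p_vs_linear = p_lin,
                                    alpha = config$alpha)),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Fractional-polynomial logistic fit\n")
  if (is.null(x$powers)) {
    cat("  continuous predictor dropped by the closed test\n")
  } else {
    cat("  selected power(s):", paste(x$powers, collapse = ", "), "\n")
  }
  cat(sprintf("  deviance: %.3f\n", x$deviance))
  co <- cbind(estimate = x$coefficients, se = x$se)
  print(round(co, 6))
  invisible(x)
}

#' Package an FP fit of the screening-results design as model coefficients
#'
#' Converts a [select_fp()] fit whose covariates were the three
#' screening-group indicators (named `group2`, `group3`, `group4`, in that
#' order) and whose continuous predictor was the 3-year base risk into a
#' [results_model_coef()] usable by the risk engine.
#'
#' @param fit an `fp_fit` with a single selected power.
#' @return a `results_model_coef`.
#' @export
as_results_model_coef <- function(fit) {
  stopifnot(inherits(fit, "fp_fit"))
  if (is.null(fit$powers) || length(fit$powers) != 1L) {
    stop("fit must have exactly one selected power to form risk-engine ",
         "coefficients", call. = FALSE)
  }
  co <- fit$coefficients
  need <- c("group2", "group3", "group4")
  if (!all(need %in% names(co))) {
    stop("fit covariates must be the screening-group indicators ",
         "group2, group3, group4", call. = FALSE)
  }
  results_model_coef(intercept = unname(co[1L]),
                     beta_group = co[need],
                     beta_fp = unname(co["fp1"]),
                     fp_power = fit$powers,
                     centering = unname(fit$centering))
}
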