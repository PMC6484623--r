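# Person-time incidence rates with confidence intervals and cumulative
# incidence of lung cancer in the presence of competing deaths.

.event_levels <- c("censored", "lung_cancer", "competing_death")

#' Build validated survival records
#'
#' @param time years of follow-up from the start of the observation window;
#'   non-negative. Follow-up is truncated at `horizon`: later events become
#'   censorings at the horizon.
#' @param event event type per record: the strings `"censored"`,
#'   `"lung_cancer"`, `"competing_death"`, or integer codes 0/1/2 in that
#'   order.
#' @param horizon truncation horizon in years (default 3, the T3-T6 window).
#' @return data.frame with columns `time` and `event` (factor).
#' @export
survival_records <- function(time, event, horizon = 3) {
  if (anyNA(time) || any(time < 0)) {
    stop("follow-up times must be non-negative", call. = FALSE)
  }
  if (is.numeric(event)) {
    if (!all(event %in% 0:2)) {
      stop("integer event codes must be 0 (censored), 1 (lung cancer), ",
           "2 (competing death)", call. = FALSE)
    }
    event <- .event_levels[event + 1L]
  }
  event <- as.character(event)
  bad <- setdiff(unique(event), .event_levels)
  if (length(bad)) {
    stop("unknown event type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(time) != length(event)) {
    stop("time and event must have equal length", call. = FALSE)
  }
  over <- time > horizon
  event[over] <- "censored"
  time[over] <- horizon
  data.frame(time = time, event = factor(event, levels = .event_levels))
}

#' Cause-specific cumulative incidence under competing risks
#'
#' Aalen-Johansen estimate of the cumulative incidence function (CIF) of
#' lung cancer, with non-lung-cancer deaths treated as competing events
#' rather than censorings. With no competing events the estimate reduces to
#' one minus the Kaplan-Meier survivor function. Ties at the same time are
#' handled in the product-limit convention: events before censorings.
#'
#' @param records a data.frame from [survival_records()] (or with
#'   compatible `time`/`event` columns).
#' @param horizon evaluation horizon in years.
#' @return object of class `cuminc_fit`: a list with `table` (columns
#'   `time`, `n_risk`, `n_event`, `cif` for the lung-cancer cause, plus
#'   `cif_death`), and `at_horizon`, the lung-cancer CIF at `horizon`.
#' @export
cumulative_incidence <- function(records, horizon = 3) {
  records <- survival_records(records$time, records$event, horizon)
  if (!any(records$event == "lung_cancer")) {
    stop("no lung cancer events in the records", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  states <- fit$states
  i_lc <- match("lung_cancer", states)
  i_cd <- match("competing_death", states)
  tab <- data.frame(time = fit$time,
                    n_risk = fit$n.risk[, 1],
                    n_event = fit$n.event[, i_lc],
                    cif = fit$pstate[, i_lc],
                    cif_death = if (is.na(i_cd)) 0 else fit$pstate[, i_cd])
  at <- if (any(tab$time <= horizon)) {
    tab$cif[max(which(tab$time <= horizon))]
  } else 0
  structure(list(table = tab, horizon = horizon, at_horizon = at,
                 n = nrow(records),
                 n_lung_cancer = sum(records$event == "lung_cancer"),
                 n_competing = sum(records$event == "competing_death")),
            class = "cuminc_fit")
}

#' @export
print.cuminc_fit <- function(x, ...) {
  cat("Cumulative incidence of lung cancer (competing risks)\n")
  cat(sprintf("  n = %d, lung cancers = %d, competing deaths = %d\n",
              x$n, x$n_lung_cancer, x$n_competing))
  cat(sprintf("  CIF at %.3g years: %.4f\n", x$horizon, x$at_horizon))
  invisible(x)
}

#' Person-time incidence rate with confidence interval
#'
#' @param events number of incident events.
#' @param person_years total person-time at risk (> 0).
#' @param per reporting scale (default per 100 000 person-years).
#' @param conf confidence level.
#' @param method `"exact"` (default) uses the exact Poisson (chi-square)
#'   interval, which reproduces published rate CIs to the printed integer;
#'   `"test_based"` uses the log-scale test-based interval
#'   `rate * exp(+/- z / sqrt(events))`.
#' @return list with `rate`, `lower`, `upper` (all on the `per` scale),
#'   `events`, `person_years`.
#' @examples
#' incidence_rate(298, 64921) # 459 (408-514) per 100 000
#' @export
incidence_rate <- function(events, person_years, per = 1e5, conf = 0.95,
                           method = c("exact", "test_based")) {
  method <- match.arg(method)
  stopifnot(events >= 0)
  if (person_years <= 0) stop("person_years must be positive", call. = FALSE)
  rate <- events / person_years * per
  a <- (1 - conf) / 2
  if (method == "exact") {
    lower <- if (events == 0) 0 else
      stats::qchisq(a, 2 * events) / 2 / person_years * per
    upper <- stats::qchisq(1 - a, 2 * (events + 1)) / 2 / person_years * per
  } else {
    if (events == 0) {
      lower <- 0
      upper <- stats::qchisq(1 - a, 2) / 2 / person_years * per
    } else {
      z <- stats::qnorm(1 - a)
      lower <- rate * exp(-z / sqrt(events))
      upper <- rate * exp(z / sqrt(events))
    }
  }
  list(rate = rate, lower = lower, upper = upper,
       events = events, person_years = person_years)
}

#' Proportion with Wilson score interval
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param conf confidence level.
#' @return list with `proportion`, `lower`, `upper`, `k`, `n`.
#' @examples
#' proportion_ci(109, 3156) # 3.5%
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(proportion = p, lower = max(0, center - half),
       upper = min(1, center + half), k = k, n = n)
}
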