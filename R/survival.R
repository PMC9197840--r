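#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator `S(t) = prod_{t_j <= t} (1 - d_j /
#' n_j)` over the distinct event times, with censored observations leaving
#' the risk set after their time (events precede censorings at tied
#' times). The fit is delegated to [survival::survfit()] and repackaged in
#' a light curve object; Greenwood standard errors are retained behind the
#' `conf` flag.
#'
#' @param time_days non-negative times in days (or a `data.frame` with
#'   columns `time_days` and `event`).
#' @param event event indicators (TRUE/1 = event, FALSE/0 = censored).
#' @param conf if `TRUE`, keep Greenwood-based confidence bounds.
#' @return Object of class `km_curve`: distinct event times `time`,
#'   survival `surv`, at-risk `n_risk` and event `n_event` counts, total
#'   `n`, and `max_time` (largest observed time, censored included).
#' @export
km_estimate <- function(time_days, event = NULL, conf = FALSE) {
  if (is.data.frame(time_days)) {
    event <- time_days$event
    time_days <- time_days$time_days
  }
  stopifnot(length(time_days) >= 1, length(time_days) == length(event))
  if (any(time_days < 0)) stop("negative survival times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time_days, as.numeric(event)) ~ 1,
                           conf.type = if (conf) "log" else "none")
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n = length(time_days), max_time = max(time_days),
                 ci_low = if (conf) fit$lower[keep] else NULL,
                 ci_high = if (conf) fit$upper[keep] else NULL),
            class = "km_curve")
}

#' Kaplan-Meier curves by stratum
#'
#' @param records `data.frame` of survival records (`time_days`, `event`,
#'   `stratum`, optionally `endpoint`).
#' @param endpoint if records carry both endpoints, which one to use
#'   (`"OS"` or `"DSS"`).
#' @param conf passed to [km_estimate()].
#' @return Named list of `km_curve` objects, one per stratum.
#' @export
km_by_stratum <- function(records, endpoint = NULL, conf = FALSE) {
  if (!is.null(endpoint) && "endpoint" %in% names(records))
    records <- records[records$endpoint == endpoint, , drop = FALSE]
  lapply(split(records, records$stratum), km_estimate, conf = conf)
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_survival(x)
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events; median %s\n",
              x$n, sum(x$n_event),
              if (is.na(med)) "not reached" else sprintf("%.0f days (%.1f y)", med, med / 365.25)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Days from primary diagnosis",
                          ylab = "Survival probability", ...) {
  t <- c(0, rep(x$time, each = 2))
  s <- c(1, 1, rep(x$surv, each = 2)[-2 * length(x$surv)])
  graphics::plot(t, s, type = "l", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation: `S(t)` equals the survival
#' after the last event time at or before `t`, and 1 before the first
#' event. Evaluation beyond the largest observed time returns the last
#' value, flagged by the `"extrapolated"` attribute.
#'
#' @param curve a [km_estimate()] result.
#' @param t_days non-negative time in days.
#' @return Survival probability, with attribute `extrapolated`.
#' @export
survival_at <- function(curve, t_days) {
  stopifnot(inherits(curve, "km_curve"), t_days >= 0)
  s <- vapply(t_days, function(t1) {
    i <- sum(curve$time <= t1)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
  attr(s, "extrapolated") <- t_days > curve$max_time
  s
}

#' Median survival time
#'
#' The smallest observed time with `S(t) <= 0.5`; `NA` (not reached) when
#' the curve never falls to one half.
#'
#' @param curve a [km_estimate()] result.
#' @return Time in days, or `NA_real_` with attribute `reached = FALSE`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  i <- which(curve$surv <= 0.5)
  if (length(i) == 0) {
    return(structure(NA_real_, reached = FALSE))
  }
  structure(curve$time[min(i)], reached = TRUE)
}
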