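#' Kaplan-Meier estimate with Greenwood accumulator
#'
#' Product-limit estimate of the probability of remaining seizure free,
#' with the Greenwood variance accumulator
#' \eqn{G(t) = \sum_{t_i \le t} d_i / (n_i (n_i - d_i))} carried
#' alongside the curve. `G` is the quantity the windowed (conditional)
#' variance of survival ratios is built from: the variance of
#' \eqn{\log \hat S(t_2)/\hat S(t_1)} is `G(t2) - G(t1)`. Pointwise 95%
#' confidence intervals use the log(-log) transform.
#'
#' `km_estimate()` is the vector interface; [km_curve()] is the
#' data-frame interface used in pipelines.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Event indicators (1 = second seizure, 0 = censored).
#' @return An `szr_km` tibble with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `greenwood` (accumulator `G`), `std_err`
#'   (of `log S`), `conf_low`, `conf_high`; the number of subjects and
#'   events are attached as attributes.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) abort("no subjects supplied")
  if (any(is.na(times)) || any(times < 0)) {
    abort("times must be non-negative and non-missing")
  }
  sf <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = "log-log", ctype = 1, stype = 1
  )
  out <- tibble::tibble(
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    surv = sf$surv
  )
  terms <- ifelse(
    out$n_event > 0,
    out$n_event / (out$n_risk * pmax(out$n_risk - out$n_event, 1e-300)),
    0
  )
  out$greenwood <- cumsum(terms)
  out$std_err <- sqrt(out$greenwood)
  loglog_ci <- km_loglog_ci(out$surv, out$greenwood)
  out$conf_low <- loglog_ci$lower
  out$conf_high <- loglog_ci$upper
  structure(out, class = c("szr_km", class(out)),
            n = length(times), n_events = sum(events))
}

km_loglog_ci <- function(surv, greenwood, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  ok <- surv > 0 & surv < 1
  lower <- upper <- rep(NA_real_, length(surv))
  se_loglog <- sqrt(greenwood[ok]) / abs(log(surv[ok]))
  lower[ok] <- surv[ok]^exp(z * se_loglog)
  upper[ok] <- surv[ok]^exp(-z * se_loglog)
  lower[surv == 1] <- 1
  upper[surv == 1] <- 1
  lower[surv == 0] <- 0
  upper[surv == 0] <- 0
  list(lower = lower, upper = upper)
}

#' Kaplan-Meier curves for a cohort, optionally by group
#'
#' @param data A cohort tibble with `time` and `event` columns.
#' @param group Optional column name (string) to stratify the curves,
#'   e.g. `"study"`, `"treatment"` or a risk-group column.
#' @return An `szr_km` tibble; with `group`, one set of rows per group
#'   identified by a `group` column.
#' @export
km_curve <- function(data, group = NULL) {
  if (is.null(group)) return(km_estimate(data$time, data$event))
  out <- data |>
    dplyr::mutate(.g = .data[[group]]) |>
    dplyr::filter(!is.na(.data$.g)) |>
    dplyr::group_by(.data$.g) |>
    dplyr::group_modify(function(d, key) {
      km_estimate(d$time, d$event)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group = ".g")
  structure(out, class = c("szr_km", class(tibble::tibble())))
}

#' Survival and numbers at risk at chosen times
#'
#' Evaluates the step-function estimate and reports the risk set just
#' before each requested time (subjects with follow-up `>= t`), the
#' number-at-risk convention used under published survival curves.
#'
#' @param km An `szr_km` (ungrouped) from [km_estimate()].
#' @param times Months at which to evaluate.
#' @return A tibble with `time`, `surv`, `n_risk`, `greenwood`.
#' @export
km_at <- function(km, times) {
  idx <- findInterval(times, km$time)
  surv <- ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
  greenwood <- ifelse(idx == 0, 0, km$greenwood[pmax(idx, 1)])
  n_total <- attr(km, "n")
  n_risk <- vapply(times, function(t) {
    if (t <= min(km$time)) {
      n_total
    } else {
      prior <- km$time < t
      if (!any(prior)) {
        n_total
      } else {
        last <- max(which(prior))
        km$n_risk[last] - km$n_event[last] - km$n_censor[last]
      }
    }
  }, numeric(1))
  tibble::tibble(time = times, surv = surv, n_risk = n_risk,
                 greenwood = greenwood)
}

#' @export
print.szr_km <- function(x, ...) {
  cat("<szr_km> product-limit estimate")
  if (!is.null(attr(x, "n"))) {
    cat(", n =", attr(x, "n"), "with", attr(x, "n_events"), "events")
  }
  cat("\n")
  NextMethod()
}
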