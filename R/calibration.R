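#' Calibration of predicted against observed survival
#'
#' Groups subjects by quantiles of their predicted survival at a horizon
#' under a fitted model, and compares the mean predicted survival in each
#' group with the Kaplan-Meier observed survival (with log(-log)
#' confidence interval) at the same horizon. A perfectly calibrated model
#' puts every point on the 45-degree line. Groups left without subjects
#' at risk at the horizon are merged with their lower-risk neighbour and
#' logged in the `"merged_groups"` attribute.
#'
#' @param data A cohort tibble.
#' @param fit An `szr_cox` fitted on the development cohort.
#' @param horizon Months at which calibration is assessed.
#' @param n_groups Number of predicted-survival quantile groups.
#' @param stratum Baseline stratum used for prediction (optional for
#'   unstratified fits).
#' @return An `szr_calibration` tibble: per group, `n`, `predicted`
#'   (mean predicted survival), `observed` (KM), `conf.low`,
#'   `conf.high`.
#' @export
calibration_data <- function(data, fit, horizon = 24, n_groups = 10,
                             stratum = NULL) {
  stopifnot(inherits(fit, "szr_cox"))
  d <- prognostic_index(data, fit)
  d <- d[!is.na(d$.pi) & !is.na(d$time) & !is.na(d$event), , drop = FALSE]
  s0h <- eval_survfn(baseline_survivor(fit, stratum), horizon)
  if (attr(s0h, "extrapolated")) {
    warn("horizon lies beyond the baseline's last event time")
  }
  d$.pred <- as.numeric(s0h)^exp(d$.pi)
  if (n_groups > 1) {
    br <- quantile(d$.pred, probs = seq(0, 1, length.out = n_groups + 1),
                   names = FALSE)
    br <- unique(br)
    d$.grp <- cut(d$.pred, breaks = br, include.lowest = TRUE,
                  labels = FALSE)
  } else {
    d$.grp <- 1L
  }
  merged <- character(0)
  repeat {
    at_risk <- tapply(d$time >= horizon, d$.grp, sum)
    empty <- names(at_risk)[at_risk == 0]
    if (length(empty) == 0) break
    g <- as.integer(empty[1])
    tgt <- if (g > 1) g - 1L else g + 1L
    merged <- c(merged, paste0("group ", g, " merged into ", tgt))
    d$.grp[d$.grp == g] <- tgt
    d$.grp <- match(d$.grp, sort(unique(d$.grp)))
  }
  out <- d |>
    dplyr::group_by(group = .data$.grp) |>
    dplyr::group_modify(function(g, key) {
      km <- km_estimate(g$time, g$event)
      at <- km_at(km, horizon)
      ci <- km_loglog_ci(at$surv, at$greenwood)
      tibble::tibble(
        n = nrow(g),
        predicted = mean(g$.pred),
        observed = at$surv,
        conf.low = ci$lower,
        conf.high = ci$upper
      )
    }) |>
    dplyr::ungroup()
  attr(out, "horizon") <- horizon
  attr(out, "merged_groups") <- merged
  class(out) <- c("szr_calibration", class(out))
  out
}
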