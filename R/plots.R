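#' Plot a Kaplan-Meier curve
#'
#' Step-function survival with pointwise log(-log) confidence bands;
#' grouped curves (per study or risk group) are coloured.
#'
#' @param object An `szr_km`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot szr_km
#' @export
autoplot.szr_km <- function(object, ...) {
  d <- tibble::as_tibble(object)
  has_group <- "group" %in% names(d)
  map <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$surv,
                 colour = .data$group, fill = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$surv)
  }
  p <- ggplot2::ggplot(d, map) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since first seizure",
                  y = "Probability seizure free",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (all(c("conf_low", "conf_high") %in% names(d))) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
                                linetype = "dashed", alpha = 0.5) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                         linetype = "dashed", alpha = 0.5)
  }
  p
}

#' Plot calibration of predicted against observed survival
#'
#' Observed (Kaplan-Meier, with confidence interval) against mean
#' predicted survival per quantile group; perfect calibration lies on
#' the 45-degree line.
#'
#' @param object An `szr_calibration`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot szr_calibration
#' @export
autoplot.szr_calibration <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted,
                                  y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = paste0("Predicted survival at ", attr(object, "horizon"),
                 " months"),
      y = "Observed survival (Kaplan-Meier)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a conditional forward-risk profile
#'
#' Risk of seizure recurrence in the next 12 months against elapsed
#' seizure-free time, with the risk threshold and its crossing time
#' marked.
#'
#' @param object An `szr_risk_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot szr_risk_profile
#' @export
autoplot.szr_risk_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  thr <- attr(object, "threshold")
  ct <- attr(object, "crossing_time")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$risk)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Seizure-free time (months)",
                  y = "Risk of seizure in next 12 months") +
    ggplot2::theme_minimal()
  if (all(c("conf.low", "conf.high") %in% names(d))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.2
    )
  }
  if (!is.na(ct) && attr(object, "crossing_status") == "crossed") {
    p <- p + ggplot2::geom_vline(xintercept = ct, colour = "blue",
                                 linetype = "dotted")
  }
  p
}
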