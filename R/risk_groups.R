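#' Risk-group cut-points on the prognostic index
#'
#' Cut-points for categorising the prognostic index into four risk
#' groups, placed at the 16th, 50th and 84th empirical centiles of the
#' development-cohort index — the grouping (due to Cox) that minimises
#' the information lost by categorising a continuous index. It yields two
#' smaller tails at relatively low and high risk and two larger
#' intermediate groups. Centiles use the linear-interpolation (type 7)
#' quantile definition.
#'
#' @param pi_values Prognostic-index values of the development cohort.
#' @param centiles Three increasing centiles in (0, 100).
#' @return An `szr_risk_grouping`: cut-points and group labels.
#' @export
cox_cut_points <- function(pi_values, centiles = c(16, 50, 84)) {
  pi_values <- pi_values[!is.na(pi_values)]
  if (length(unique(pi_values)) < 4) {
    abort("need at least 4 distinct prognostic-index values")
  }
  stopifnot(length(centiles) == 3, !is.unsorted(centiles))
  cuts <- quantile(pi_values, probs = centiles / 100, type = 7,
                   names = FALSE)
  if (any(diff(cuts) <= 0)) {
    abort(paste0("tied prognostic-index values give duplicate cut-points",
                 "; consider different centiles"))
  }
  structure(
    list(
      cut_points = cuts,
      centiles = centiles,
      labels = c("low", "moderately_low", "moderately_high", "high")
    ),
    class = "szr_risk_grouping"
  )
}

#' @export
print.szr_risk_grouping <- function(x, ...) {
  cat("<szr_risk_grouping> cut-points at centiles ",
      paste(x$centiles, collapse = "/"), ": ",
      paste(signif(x$cut_points, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign subjects to risk groups
#'
#' Half-open assignment with the boundary in the lower group:
#' `pi <= c1` is low, `c1 < pi <= c2` moderately low, `c2 < pi <= c3`
#' moderately high, `pi > c3` high. Cut-points are always computed on
#' the development cohort and then applied unchanged to any validation
#' cohort's index — transporting the grouping is the point.
#'
#' @param data A cohort tibble carrying a `.pi` column (from
#'   [prognostic_index()]), or a numeric vector of index values.
#' @param grouping An `szr_risk_grouping` from [cox_cut_points()].
#' @return For a cohort, the cohort with a `risk_group` ordered factor
#'   appended; for a vector, the factor itself.
#' @export
assign_groups <- function(data, grouping) {
  stopifnot(inherits(grouping, "szr_risk_grouping"))
  pi_values <- if (is.data.frame(data)) data$.pi else data
  grp <- cut(pi_values,
             breaks = c(-Inf, grouping$cut_points, Inf),
             labels = grouping$labels, right = TRUE, ordered_result = TRUE)
  if (is.data.frame(data)) {
    data$risk_group <- grp
    data
  } else {
    grp
  }
}

#' Hazard ratios between risk groups
#'
#' Cox fit on the three upper risk-group indicators with the low group
#' as reference; Wald 95% confidence intervals. An empty group's
#' contrast is reported as `NA` and logged with a warning.
#'
#' @param data A cohort tibble with a `risk_group` column (see
#'   [assign_groups()]).
#' @return A tibble: `comparison`, `estimate` (log HR), `hazard_ratio`,
#'   `conf.low`, `conf.high` (on the HR scale), `n`, `n_events`.
#' @export
group_hazard_ratios <- function(data) {
  if (!"risk_group" %in% names(data)) abort("no risk_group column")
  d <- data[!is.na(data$risk_group) & !is.na(data$time) &
              !is.na(data$event), , drop = FALSE]
  lev <- levels(d$risk_group)
  present <- lev[lev %in% unique(as.character(d$risk_group))]
  if (!"low" %in% present || sum(d$event[d$risk_group == "low"]) < 1) {
    abort("the low risk group must contain at least one event")
  }
  g <- factor(as.character(d$risk_group), levels = present)
  fit <- survival::coxph(survival::Surv(d$time, d$event) ~ g,
                         ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  done <- tibble::tibble(
    comparison = paste0(sub("^g", "", names(beta)), "_vs_low"),
    estimate = unname(beta),
    hazard_ratio = exp(unname(beta)),
    conf.low = exp(unname(beta - qnorm(0.975) * se)),
    conf.high = exp(unname(beta + qnorm(0.975) * se))
  )
  absent <- setdiff(setdiff(lev, "low"), present)
  if (length(absent) > 0) {
    warn(paste0("empty risk group(s), contrast undefined: ",
                paste(absent, collapse = ", ")))
    done <- dplyr::bind_rows(done, tibble::tibble(
      comparison = paste0(absent, "_vs_low"),
      estimate = NA_real_, hazard_ratio = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_
    ))
  }
  counts <- d |>
    dplyr::group_by(
      comparison = paste0(as.character(.data$risk_group), "_vs_low")
    ) |>
    dplyr::summarise(n = dplyr::n(), n_events = sum(.data$event),
                     .groups = "drop")
  dplyr::left_join(done, counts, by = "comparison")
}

#' Kaplan-Meier curves per risk group
#'
#' Product-limit curves for each risk group, used to inspect both
#' discrimination (separation of the curves; wider separation goes with
#' larger between-group hazard ratios) and calibration (agreement of a
#' group's curve between development and validation cohorts).
#'
#' @param data A cohort tibble with a `risk_group` column.
#' @return An `szr_km` tibble with a `group` column.
#' @export
group_km <- function(data) {
  if (!"risk_group" %in% names(data)) abort("no risk_group column")
  km_curve(data, group = "risk_group")
}

#' Months for which a group's cumulative risk stays below a bound
#'
#' Scans a group's Kaplan-Meier curve for the last time up to which the
#' cumulative seizure-recurrence risk `1 - S(t)` remains below `bound`;
#' low-risk patients typically stay below a 20% cumulative risk for an
#' extended period after the index seizure.
#'
#' @param km An ungrouped `szr_km` (e.g. one group's rows).
#' @param bound Cumulative risk bound (default 0.20).
#' @return Months until the bound is first reached (`Inf` if never
#'   within follow-up).
#' @export
km_time_below <- function(km, bound = 0.2) {
  crossed <- km$surv < 1 - bound
  if (!any(crossed)) return(Inf)
  km$time[which(crossed)[1]]
}
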