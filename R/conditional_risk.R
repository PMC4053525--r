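#' Forward 12-month seizure risk at an elapsed seizure-free time
#'
#' The risk of a second seizure in the next `window` months for someone
#' who has already been seizure free for `t` months:
#' `risk(t) = 1 - S(t + window) / S(t)`.
#'
#' For a Kaplan-Meier curve the variance of the log survival ratio is
#' the Greenwood sum restricted to the window,
#' \eqn{\sum_{t < t_i \le t+w} d_i/(n_i(n_i-d_i))} — equivalently the
#' difference of the Greenwood accumulator at the window ends — and the
#' 95% confidence interval is formed on the log ratio and complemented.
#' With the window anchored at 0 this reduces to the usual Greenwood
#' variance. For a piecewise-linear survivor function ([survfn()],
#' [pattern_survfn()]) only the point estimate is returned; model-based
#' intervals come from [pattern_risk_profile()]'s bootstrap.
#'
#' @param s An `szr_km` (ungrouped) or an `szr_survfn`.
#' @param t Elapsed seizure-free times (months).
#' @param window Forward window (months, default 12).
#' @return A tibble: `t`, `risk`, and for KM input `conf.low`,
#'   `conf.high`.
#' @export
forward_risk <- function(s, t, window = 12) {
  if (any(t < 0)) abort("t must be >= 0")
  if (inherits(s, "szr_km")) {
    if ("group" %in% names(s)) {
      abort("supply a single group's curve, not a grouped szr_km")
    }
    support_end <- max(s$time)
    if (any(t + window > support_end)) {
      abort(paste0("window extends beyond the last observed time (",
                   format(support_end), " months)"))
    }
    a <- km_at(s, t)
    b <- km_at(s, t + window)
    if (any(a$surv <= 0)) abort("S(t) = 0: forward risk undefined")
    ratio <- b$surv / a$surv
    var_log <- pmax(b$greenwood - a$greenwood, 0)
    se <- sqrt(var_log)
    z <- qnorm(0.975)
    r_low <- ratio * exp(-z * se)
    r_high <- pmin(ratio * exp(z * se), 1)
    tibble::tibble(
      t = t,
      risk = 1 - ratio,
      conf.low = 1 - r_high,
      conf.high = pmin(pmax(1 - r_low, 1 - ratio), 1)
    )
  } else if (inherits(s, "szr_survfn")) {
    support_end <- survfn_support_end(s)
    if (any(t + window > support_end)) {
      abort(paste0("window extends beyond the supported range (",
                   format(support_end), " months)"))
    }
    ratio <- conditional_survivor(s, t, t + window)
    tibble::tibble(t = t, risk = 1 - ratio)
  } else {
    abort("s must be an szr_km or an szr_survfn")
  }
}

#' Table of forward 12-month risks per treatment arm
#'
#' Unadjusted (Kaplan-Meier based) estimates of the risk of seizure
#' recurrence over the next 12 months at a set of elapsed seizure-free
#' times, per treatment policy, with numbers at risk — the layout used
#' to compare immediate and delayed treatment at 6, 12, 18 and 24
#' months. Risks and confidence limits are rounded to whole percent in
#' the `label` column; unrounded values are kept alongside.
#'
#' @param data A pooled cohort tibble with `treatment`, `time`, `event`.
#' @param times Elapsed seizure-free times (months).
#' @param window Forward window (months).
#' @return A tibble: `treatment`, `time`, `n_risk`, `risk`, `conf.low`,
#'   `conf.high` (proportions), `risk_pct`, `label`.
#' @export
risk_table <- function(data, times = c(6, 12, 18, 24), window = 12) {
  arms <- levels(factor(data$treatment))
  purrr::map_dfr(arms, function(arm) {
    d <- data[!is.na(data$treatment) & data$treatment == arm, ,
              drop = FALSE]
    km <- km_estimate(d$time, d$event)
    fr <- forward_risk(km, times, window = window)
    at <- km_at(km, times)
    tibble::tibble(
      treatment = arm,
      time = times,
      n_risk = at$n_risk,
      risk = fr$risk,
      conf.low = fr$conf.low,
      conf.high = fr$conf.high,
      risk_pct = round(100 * fr$risk),
      label = sprintf("%d (%d to %d)", round(100 * fr$risk),
                      round(100 * fr$conf.low),
                      round(100 * fr$conf.high))
    )
  })
}

#' Conditional 12-month risk profile for a covariate pattern
#'
#' Model-based risk of seizure recurrence in the next `window` months as
#' a function of elapsed seizure-free time, for a covariate pattern
#' under a fitted model (predicted survival
#' `S0(t)^exp(lp)` on the piecewise-linear baseline). Optionally, 95%
#' confidence bands from a nonparametric bootstrap: subjects are
#' resampled within strata, the model refitted and the profile
#' recomputed. The time at which the risk first falls to or below
#' `threshold` is located by [threshold_time()] and attached, together
#' with its status, as attributes.
#'
#' @param data Cohort tibble the model was (or can be) fitted on; needed
#'   only when `conf = "bootstrap"`.
#' @param fit An `szr_cox`.
#' @param pattern Named list of covariate levels (see [pattern_lp()]).
#' @param stratum Baseline stratum (optional for unstratified fits).
#' @param t_grid Elapsed-time grid (months).
#' @param window Forward window (months).
#' @param threshold Risk threshold searched for (default 0.20, the
#'   regulatory bound for returning to drive; configurable).
#' @param conf `"none"` or `"bootstrap"`.
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return An `szr_risk_profile` tibble: `t`, `risk` (+ `conf.low`,
#'   `conf.high` under bootstrap), with `crossing_time`,
#'   `crossing_status`, `pattern` attributes.
#' @export
pattern_risk_profile <- function(fit, pattern = list(), stratum = NULL,
                                 t_grid = seq(0, 24, by = 0.5),
                                 window = 12, threshold = 0.2,
                                 conf = c("none", "bootstrap"), B = 500,
                                 seed = 1, data = NULL) {
  conf <- match.arg(conf)
  s <- pattern_survfn(fit, pattern, stratum)
  support_end <- survfn_support_end(s)
  t_grid <- t_grid[t_grid + window <= support_end]
  if (length(t_grid) == 0) {
    abort(paste0("no grid point has t + window within the supported ",
                 "range (", format(support_end), " months)"))
  }
  out <- forward_risk(s, t_grid, window = window)
  if (conf == "bootstrap") {
    if (is.null(data)) abort("bootstrap confidence bands need `data`")
    strata_var <- fit$spec$strata
    groups <- if (is.null(strata_var)) rep("(all)", nrow(data)) else
      as.character(data[[strata_var]])
    idx_by <- split(seq_len(nrow(data)), groups)
    reps <- withr::with_seed(seed, {
      purrr::map(seq_len(B), function(b) {
        idx <- unlist(lapply(idx_by, function(ii) {
          ii[sample.int(length(ii), length(ii), replace = TRUE)]
        }), use.names = FALSE)
        bd <- data[idx, , drop = FALSE]
        bd$subject_id <- sprintf("b%07d", seq_len(nrow(bd)))
        bf <- try(fit_cox(bd, fit$spec, ties = fit$ties), silent = TRUE)
        if (inherits(bf, "try-error")) return(rep(NA_real_,
                                                  length(t_grid)))
        bs <- try(pattern_survfn(bf, pattern, stratum), silent = TRUE)
        if (inherits(bs, "try-error")) return(rep(NA_real_,
                                                  length(t_grid)))
        vapply(t_grid, function(tt) {
          if (tt + window > survfn_support_end(bs)) return(NA_real_)
          1 - conditional_survivor(bs, tt, tt + window)
        }, numeric(1))
      })
    })
    mat <- do.call(rbind, reps)
    out$conf.low <- apply(mat, 2, quantile, probs = 0.025, na.rm = TRUE)
    out$conf.high <- apply(mat, 2, quantile, probs = 0.975, na.rm = TRUE)
  }
  cross <- threshold_time(
    function(tt) 1 - conditional_survivor(s, tt, tt + window),
    threshold = threshold,
    range = c(min(t_grid), max(t_grid))
  )
  structure(out,
            class = c("szr_risk_profile", class(out)),
            crossing_time = cross$time,
            crossing_status = cross$status,
            threshold = threshold,
            pattern = pattern)
}

#' Time at which forward risk falls below a threshold
#'
#' Finds the smallest elapsed seizure-free time in `range` at which a
#' continuous forward-risk function is at or below `threshold` — e.g.
#' the time point from which the 12-month recurrence risk is below the
#' 20% bound used in driving regulations. The crossing is bracketed on a
#' fine grid and refined by bisection, then reported to one decimal
#' month. If the risk is already at or below the threshold at the range
#' start the start is returned with status `"already_below"`; if the
#' risk never reaches the threshold the time is `NA` with status
#' `"never_below"`.
#'
#' @param risk_fn Function of elapsed time returning the forward risk
#'   (continuous on `range`; risk built on a piecewise-linear survivor
#'   is).
#' @param threshold Risk threshold (default 0.20).
#' @param range Search range in months.
#' @return A one-row tibble: `time` (1-decimal months or `NA`),
#'   `status` (`"crossed"`, `"already_below"` or `"never_below"`),
#'   `threshold`.
#' @export
threshold_time <- function(risk_fn, threshold = 0.2, range = c(0, 24)) {
  lo <- range[1]; hi <- range[2]
  if (risk_fn(lo) <= threshold) {
    return(tibble::tibble(time = round(lo, 1), status = "already_below",
                          threshold = threshold))
  }
  grid <- seq(lo, hi, length.out = max(201, ceiling((hi - lo) / 0.05)))
  vals <- vapply(grid, risk_fn, numeric(1))
  below <- which(vals <= threshold)
  if (length(below) == 0) {
    return(tibble::tibble(time = NA_real_, status = "never_below",
                          threshold = threshold))
  }
  j <- below[1]
  a <- grid[j - 1]; b <- grid[j]
  for (k in seq_len(60)) {
    mid <- (a + b) / 2
    if (risk_fn(mid) <= threshold) b <- mid else a <- mid
    if (b - a < 1e-4) break
  }
  tibble::tibble(time = round(b, 1), status = "crossed",
                 threshold = threshold)
}

#' @export
print.szr_risk_profile <- function(x, ...) {
  ct <- attr(x, "crossing_time")
  cat("<szr_risk_profile> forward risk on ", nrow(x), " grid points; ",
      100 * attr(x, "threshold"), "% threshold ",
      switch(attr(x, "crossing_status"),
             crossed = paste0("crossed at ", ct, " months"),
             already_below = paste0("already below at ", ct, " months"),
             never_below = "never reached"),
      "\n", sep = "")
  NextMethod()
}
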