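#' Piecewise-linear survivor functions
#'
#' A survivor function is represented by its value at a set of knots
#' (time 0 with survival 1, plus the event times), joined by linear
#' interpolation — the piecewise-linear assumption used when reading
#' continuous risk off a step-function baseline. Beyond the last knot the
#' function is held constant and evaluation is flagged as extrapolated;
#' threshold searches refuse to report crossings there.
#'
#' @param time Knot times (months), strictly increasing, starting at or
#'   after 0.
#' @param surv Survivor values at the knots, non-increasing, in `[0, 1]`.
#' @return An `szr_survfn`.
#' @export
survfn <- function(time, surv) {
  if (length(time) != length(surv)) abort("time and surv lengths differ")
  if (is.unsorted(time, strictly = TRUE)) {
    abort("knot times must be strictly increasing")
  }
  if (any(diff(surv) > 1e-12)) abort("survivor values must be non-increasing")
  if (any(surv < 0 | surv > 1)) abort("survivor values must lie in [0, 1]")
  if (time[1] > 0) {
    time <- c(0, time)
    surv <- c(1, surv)
  }
  structure(list(time = time, surv = surv), class = "szr_survfn")
}

#' Evaluate a piecewise-linear survivor function
#'
#' @param s An `szr_survfn`.
#' @param t Times (months) at which to evaluate.
#' @return Survivor values; the `"extrapolated"` attribute marks entries
#'   beyond the last knot (held at the last value).
#' @export
eval_survfn <- function(s, t) {
  stopifnot(inherits(s, "szr_survfn"))
  if (any(t < 0)) abort("t must be >= 0")
  out <- approx(s$time, s$surv, xout = t, rule = 2)$y
  attr(out, "extrapolated") <- t > max(s$time)
  out
}

#' @export
print.szr_survfn <- function(x, ...) {
  cat("<szr_survfn> piecewise-linear survivor, ", length(x$time),
      " knots on [0, ", format(max(x$time)), "] months\n", sep = "")
  invisible(x)
}

#' Last non-extrapolated time of a survivor function
#' @param s An `szr_survfn`.
#' @return The last knot time in months.
#' @export
survfn_support_end <- function(s) max(s$time)

#' Baseline survivor function of a fitted model
#'
#' The Breslow-type baseline cumulative hazard of a stratum is converted
#' to a survivor function `S0 = exp(-H0)` stepped at the event times and
#' then joined piecewise-linearly, yielding the continuous baseline from
#' which per-pattern annual risks are read.
#'
#' @param fit An `szr_cox`.
#' @param stratum Stratum label; may be omitted for an unstratified fit.
#' @return An `szr_survfn`.
#' @export
baseline_survivor <- function(fit, stratum = NULL) {
  stopifnot(inherits(fit, "szr_cox"))
  available <- unique(fit$baseline$stratum)
  if (is.null(stratum)) {
    if (length(available) > 1) {
      abort(paste0("fit has multiple strata; choose one of: ",
                   paste(available, collapse = ", ")))
    }
    stratum <- available
  }
  if (!stratum %in% available) {
    abort(paste0("unknown stratum: ", stratum))
  }
  b <- fit$baseline[fit$baseline$stratum == stratum, ]
  survfn(b$time, b$surv)
}

#' Predicted survival for a covariate pattern
#'
#' `S(t | pattern) = S0(t) ^ exp(lp)` where `lp` is the pattern's
#' prognostic index under the fit and `S0` the (piecewise-linear)
#' baseline survivor of the chosen stratum.
#'
#' @param fit An `szr_cox`.
#' @param pattern Named list of covariate levels (omitted covariates at
#'   reference); see [pattern_lp()].
#' @param t Times (months).
#' @param stratum Stratum label (optional for unstratified fits).
#' @return Survival probabilities with the `"extrapolated"` attribute of
#'   [eval_survfn()].
#' @export
predict_survivor <- function(fit, pattern = list(), t, stratum = NULL) {
  if (any(t < 0)) abort("t must be >= 0")
  s0 <- baseline_survivor(fit, stratum)
  lp <- pattern_lp(fit, pattern)
  base <- eval_survfn(s0, t)
  out <- base^exp(lp)
  attr(out, "extrapolated") <- attr(base, "extrapolated")
  out
}

#' Pattern-level survivor function
#'
#' The piecewise-linear survivor of a covariate pattern, i.e. the
#' baseline knots with survivor values raised to `exp(lp)`.
#'
#' @inheritParams predict_survivor
#' @return An `szr_survfn`.
#' @export
pattern_survfn <- function(fit, pattern = list(), stratum = NULL) {
  s0 <- baseline_survivor(fit, stratum)
  lp <- pattern_lp(fit, pattern)
  survfn(s0$time, s0$surv^exp(lp))
}

#' Conditional probability of remaining seizure free
#'
#' The probability of remaining seizure free to `t2` given seizure
#' freedom to `t1`, computed as `S(t2) / S(t1)` — for example, the
#' probability of being seizure free for 18 months divided by the
#' probability of being seizure free for six months.
#'
#' @param s An `szr_survfn`, or any function of time returning survival
#'   probabilities.
#' @param t1,t2 Months with `0 <= t1 <= t2`.
#' @return The conditional survival probability.
#' @export
conditional_survivor <- function(s, t1, t2) {
  if (any(t1 < 0) || any(t2 < t1)) abort("need 0 <= t1 <= t2")
  f <- if (inherits(s, "szr_survfn")) function(t) eval_survfn(s, t) else s
  s1 <- as.numeric(f(t1))
  if (any(s1 <= 0)) abort("S(t1) = 0: conditional survival undefined")
  as.numeric(f(t2)) / s1
}
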