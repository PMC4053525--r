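#' Fit the proportional-hazards model
#'
#' Fits the Cox model defined by a [model_spec()] to a cohort, maximising
#' the partial likelihood with Efron tie handling (switchable to
#' Breslow), optionally stratified so that each study keeps its own
#' baseline hazard while sharing covariate effects. Subjects with a
#' missing value on any covariate used by the specification are excluded
#' (complete-case) and counted in the fit object. The per-stratum
#' baseline cumulative hazard is the Breslow-type estimator evaluated at
#' the fitted coefficients for the reference covariate pattern.
#'
#' @param data A cohort tibble.
#' @param spec A `szr_spec`; its `strata` field (e.g. `"study"`) selects
#'   stratified fitting.
#' @param ties Tie-handling approximation for the partial likelihood.
#' @return An `szr_cox` object: coefficients (log hazard ratios), their
#'   covariance, per-stratum baseline cumulative hazard, and counts.
#'   [tidy()] returns the coefficient table with Wald 95% confidence
#'   intervals; [glance()] the fit summary.
#' @export
fit_cox <- function(data, spec = default_model_spec(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(spec, "szr_spec"))
  used_vars <- unique(spec$terms$variable)
  complete <- stats::complete.cases(data[, used_vars, drop = FALSE]) &
    !is.na(data$time) & !is.na(data$event)
  n_excluded <- sum(!complete)
  d <- data[complete, , drop = FALSE]
  if (nrow(d) == 0) abort("no complete cases on the model covariates")
  X <- spec_matrix(d, spec)
  strata_var <- spec$strata
  if (!is.null(strata_var)) {
    stratum <- as.character(d[[strata_var]])
    ev_per <- tapply(d$event, stratum, sum)
    if (any(ev_per < 1)) {
      warn(paste0("stratum with no events: ",
                  paste(names(ev_per)[ev_per < 1], collapse = ", ")))
    }
    fit <- survival::coxph(
      survival::Surv(d$time, d$event) ~ X + survival::strata(stratum),
      ties = ties
    )
  } else {
    stratum <- rep("(all)", nrow(d))
    fit <- survival::coxph(survival::Surv(d$time, d$event) ~ X,
                           ties = ties)
  }
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    bad <- colnames(X)[!is.finite(beta) | abs(beta) > 15]
    abort(paste0("likely monotone likelihood (separation) for term(s): ",
                 paste(bad, collapse = ", ")))
  }
  V <- stats::vcov(fit)
  dimnames(V) <- list(colnames(X), colnames(X))
  lp <- drop(X %*% beta)
  baseline <- breslow_basehaz(d$time, d$event, lp, stratum)
  structure(
    list(
      coefficients = beta,
      vcov = V,
      spec = spec,
      baseline = baseline,
      n = nrow(d),
      n_events = sum(d$event),
      n_excluded = n_excluded,
      ties = ties,
      loglik = fit$loglik,
      iter = fit$iter
    ),
    class = "szr_cox"
  )
}

# Breslow cumulative-hazard estimator per stratum:
# H0(t) = sum_{event times <= t} d_i / sum_{at risk} exp(lp)
breslow_basehaz <- function(time, event, lp, stratum) {
  purrr::map_dfr(unique(stratum), function(s) {
    sel <- stratum == s
    t_s <- time[sel]; e_s <- event[sel]; r_s <- exp(lp[sel])
    et <- sort(unique(t_s[e_s == 1]))
    if (length(et) == 0) {
      return(tibble::tibble(stratum = s, time = numeric(0),
                            cumhaz = numeric(0), surv = numeric(0)))
    }
    ord <- order(t_s)
    ts <- t_s[ord]
    cs <- c(0, cumsum(r_s[ord]))
    total_r <- cs[length(cs)]
    # subjects leaving the risk set before tt: those with t < tt
    n_before <- findInterval(et, ts, left.open = TRUE)
    denom <- total_r - cs[n_before + 1]
    d <- vapply(split(e_s, factor(t_s))[as.character(et)], sum,
                numeric(1))
    H <- cumsum(d / denom)
    tibble::tibble(stratum = s, time = et, cumhaz = unname(H),
                   surv = exp(-unname(H)))
  })
}

#' @export
print.szr_cox <- function(x, ...) {
  cat("<szr_cox> ", length(x$coefficients), " terms, n = ", x$n,
      " (", x$n_events, " events, ", x$n_excluded,
      " excluded incomplete), ties = ", x$ties, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy szr_cox
#' @export
tidy.szr_cox <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se))),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @method glance szr_cox
#' @export
glance.szr_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, n_excluded = x$n_excluded,
    logLik = x$loglik[length(x$loglik)], iter = x$iter[1],
    n_strata = length(unique(x$baseline$stratum))
  )
}

#' Prognostic index (linear predictor)
#'
#' Adds the prognostic index `pi = x * beta` to a cohort under a fitted
#' model; the reference covariate pattern maps to 0. Subjects missing a
#' value on a covariate used by the model get `NA`.
#'
#' @param data A cohort tibble.
#' @param fit An `szr_cox`.
#' @return `data` with a `.pi` column appended.
#' @export
prognostic_index <- function(data, fit) {
  stopifnot(inherits(fit, "szr_cox"))
  X <- spec_matrix(data, fit$spec)
  data$.pi <- drop(X %*% fit$coefficients)
  n_na <- sum(is.na(data$.pi))
  if (n_na > 0) {
    inform(paste0(n_na, " subject(s) have missing prognostic index ",
                  "(incomplete covariates)"))
  }
  data
}

#' Linear predictor of a single covariate pattern
#'
#' @param fit An `szr_cox`.
#' @param pattern A named list/vector of covariate levels, e.g.
#'   `list(aetiology = "remote_symptomatic", eeg = "abnormal")`.
#'   Covariates omitted from the pattern sit at their reference level.
#' @return The prognostic index of the pattern (0 for the reference).
#' @export
pattern_lp <- function(fit, pattern = list()) {
  stopifnot(inherits(fit, "szr_cox"))
  lv <- cohort_levels()
  terms <- fit$spec$terms
  lp <- 0
  for (var in names(pattern)) {
    level <- as.character(pattern[[var]])
    if (!var %in% names(lv) || !level %in% lv[[var]]) {
      abort(paste0("invalid pattern entry: ", var, " = ", level))
    }
    hit <- terms$variable == var & terms$level == level
    if (any(hit)) lp <- lp + fit$coefficients[terms$term[hit]]
  }
  unname(lp)
}
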