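#' Run the external-validation workflow
#'
#' Orchestrates the full validation of a development-cohort prognostic
#' model against every other study in a pooled cohort table:
#' discrimination via Harrell's c-index and the concordance-difference
#' rule, calibration at a horizon, and transported risk groups with
#' per-group hazard ratios and Kaplan-Meier curves (including the
#' low-risk overlay across cohorts).
#'
#' A validation study that never collected a model covariate (all-`NA`
#' column, as for seizures-while-asleep in FIRST) is handled by every
#' requested missing-covariate method: variable matching refits a
#' reduced model on the development cohort, the four imputation schemes
#' fill the column from the development data. If such a study also
#' lacks the "not clinically indicated" EEG/imaging category entirely,
#' the development cohort is collapsed to the two-level coding first and
#' the comparator model refitted, so like is compared with like.
#'
#' @param data Pooled cohort tibble (a `study` column distinguishes the
#'   cohorts).
#' @param development Study label of the development cohort.
#' @param spec Model specification for the development model.
#' @param horizon Calibration horizon (months).
#' @param centiles Risk-group centiles.
#' @param tol Concordance-difference bound for the generalisability
#'   verdict.
#' @param imputation_methods Missing-covariate methods to run.
#' @param M Draws for the multiple-random-selection method.
#' @param seed Integer seed for the imputation draws.
#' @return An `szr_validation_report` list: `concordance` (one row per
#'   dataset/method with c, CI, delta and verdict), `calibration`
#'   (named list), `risk_groups` (`hr_table`, `km`, `groupings`),
#'   `low_risk_km`, `fits`, `config`.
#' @export
run_external_validation <- function(data, development = "MESS",
                                    spec = default_model_spec(),
                                    horizon = 24,
                                    centiles = c(16, 50, 84),
                                    tol = 0.05,
                                    imputation_methods =
                                      c("variable_matching",
                                        "random_selection", "proportion",
                                        "hot_deck", "multiple_random"),
                                    M = 10, seed = 1) {
  studies <- unique(as.character(data$study))
  if (!development %in% studies) {
    abort(paste0("development study not in data: ", development))
  }
  dev <- data[data$study == development, , drop = FALSE]
  fits <- list()
  conc_rows <- list()
  calib <- list()
  hr_rows <- list()
  km_rows <- list()
  groupings <- list()
  low_risk_rows <- list()

  # one comparator context per covariate scheme (full, reduced, ...)
  comparator <- function(label, dev_data, cspec) {
    fit <- fit_cox(dev_data, cspec)
    scored <- prognostic_index(dev_data, fit)
    cc <- harrell_c(scored$time, scored$event, scored$.pi)
    grouping <- cox_cut_points(scored$.pi[!is.na(scored$.pi)], centiles)
    grouped <- assign_groups(scored, grouping)
    list(label = label, fit = fit, c = cc, grouping = grouping,
         grouped = grouped)
  }

  record_groups <- function(dataset_label, grouped) {
    hr <- group_hazard_ratios(grouped)
    hr$dataset <- dataset_label
    hr_rows[[dataset_label]] <<- hr
    km <- group_km(grouped)
    km$dataset <- dataset_label
    km_rows[[dataset_label]] <<- km
    low <- grouped[!is.na(grouped$risk_group) &
                     grouped$risk_group == "low", , drop = FALSE]
    lkm <- km_estimate(low$time, low$event)
    lkm$dataset <- dataset_label
    low_risk_rows[[dataset_label]] <<- lkm
  }

  full <- comparator(development, dev, spec)
  fits[[development]] <- full$fit
  conc_rows[[development]] <- dplyr::bind_cols(
    tibble::tibble(dataset = development, method = "development"),
    full$c, tibble::tibble(delta = NA_real_, generalises = NA)
  )
  groupings[[development]] <- full$grouping
  record_groups(development, full$grouped)

  validate_against <- function(dataset_label, vd, comp) {
    scored <- prognostic_index(vd, comp$fit)
    cc <- harrell_c(scored$time, scored$event, scored$.pi)
    dd <- concordance_difference(comp$c, cc, tol = tol)
    conc_rows[[dataset_label]] <<- dplyr::bind_cols(
      tibble::tibble(dataset = dataset_label, method = comp$label),
      cc, dd
    )
    calib[[dataset_label]] <<- calibration_data(vd, comp$fit,
                                                horizon = horizon)
    record_groups(dataset_label, assign_groups(scored, comp$grouping))
  }

  for (v in setdiff(studies, development)) {
    vd <- data[data$study == v, , drop = FALSE]
    model_vars <- unique(spec$terms$variable)
    unavailable <- model_vars[!vapply(model_vars, covariate_available,
                                      logical(1), data = vd)]
    if (length(unavailable) == 0) {
      validate_against(v, vd, full)
      next
    }
    # match the validation study's category scheme before comparing
    has_ni <- any(spec$terms$level == "not_indicated")
    val_two_level <- has_ni &&
      !any(vd$eeg == "not_indicated", na.rm = TRUE) &&
      !any(vd$imaging == "not_indicated", na.rm = TRUE)
    dev_v <- if (val_two_level) collapse_two_level(dev) else dev
    spec_v <- if (val_two_level) {
      model_spec(spec$terms[spec$terms$level != "not_indicated",
                            c("variable", "level")],
                 strata = spec$strata)
    } else {
      spec
    }
    for (mv in unavailable) {
      for (method in imputation_methods) {
        label <- paste0(v, ": ", method)
        if (method == "variable_matching") {
          comp_label <- paste0(development, ": no ", mv)
          if (is.null(fits[[comp_label]])) {
            comp <- comparator(comp_label, dev_v,
                               drop_spec_variable(spec_v, mv))
            fits[[comp_label]] <- comp$fit
            conc_rows[[comp_label]] <- dplyr::bind_cols(
              tibble::tibble(dataset = comp_label,
                             method = "development"),
              comp$c,
              tibble::tibble(delta = NA_real_, generalises = NA)
            )
            groupings[[comp_label]] <- comp$grouping
            record_groups(comp_label, comp$grouped)
            assign(".vm_comp", comp, inherits = FALSE)
          }
          validate_against(label, vd, get(".vm_comp"))
        } else {
          comp_label <- paste0(development, ": with ", mv)
          if (is.null(fits[[comp_label]])) {
            comp2 <- comparator(comp_label, dev_v, spec_v)
            fits[[comp_label]] <- comp2$fit
            conc_rows[[comp_label]] <- dplyr::bind_cols(
              tibble::tibble(dataset = comp_label,
                             method = "development"),
              comp2$c,
              tibble::tibble(delta = NA_real_, generalises = NA)
            )
            groupings[[comp_label]] <- comp2$grouping
            record_groups(comp_label, comp2$grouped)
            assign(".imp_comp", comp2, inherits = FALSE)
          }
          vd_imp <- impute_missing_covariate(
            dev_v, vd, missing_var = mv, method = method, M = M,
            seed = seed
          )
          validate_against(label, vd_imp, get(".imp_comp"))
        }
      }
    }
  }

  structure(
    list(
      development = development,
      concordance = dplyr::bind_rows(conc_rows),
      calibration = calib,
      risk_groups = list(
        groupings = groupings,
        hr_table = dplyr::bind_rows(hr_rows),
        km = dplyr::bind_rows(km_rows)
      ),
      low_risk_km = dplyr::bind_rows(low_risk_rows),
      fits = fits,
      config = list(development = development, horizon = horizon,
                    centiles = centiles, tol = tol,
                    imputation_methods = imputation_methods, M = M,
                    seed = seed)
    ),
    class = "szr_validation_report"
  )
}

#' @export
print.szr_validation_report <- function(x, ...) {
  cat("<szr_validation_report> development:", x$development, "\n")
  print(x$concordance)
  invisible(x)
}

#' Fit the model to the pooled super-population
#'
#' Pools all cohorts, fits the prognostic model stratified by study
#' (shared coefficients, per-study baseline hazards), refits on
#' configured study subsets as sensitivity analyses, tabulates the
#' unadjusted forward 12-month risks per treatment arm, and computes
#' conditional risk profiles with threshold-crossing times for a set of
#' covariate patterns.
#'
#' @param data Pooled cohort tibble with a `study` column.
#' @param spec Model specification; its strata default to `"study"`.
#' @param times Elapsed times for the per-arm risk table (months).
#' @param window Forward window (months).
#' @param patterns Named list of covariate patterns for risk profiles;
#'   defaults to the aetiology x EEG x imaging x treatment combinations
#'   with seizures not confined to sleep and no first-degree relative
#'   with epilepsy.
#' @param t_grid Elapsed-time grid for the profiles.
#' @param threshold Forward-risk threshold (default 0.20).
#' @param stratum Baseline stratum used for the profiles (default the
#'   first study).
#' @param exclude List of study subsets to drop in sensitivity refits.
#' @return An `szr_superpop_report` list: `fit`, `estimates` (tidy
#'   coefficient table with hazard ratios), `sensitivity`,
#'   `risk_table`, `profiles`, `crossings`, `config`.
#' @export
run_superpopulation <- function(data, spec = default_model_spec(),
                                times = c(6, 12, 18, 24), window = 12,
                                patterns = NULL,
                                t_grid = seq(0, 24, by = 0.5),
                                threshold = 0.2, stratum = NULL,
                                exclude = list("FIRST", "WA")) {
  studies <- unique(as.character(data$study))
  if (length(studies) < 2) {
    abort("a pooled analysis needs at least two studies")
  }
  if (is.null(spec$strata)) spec$strata <- "study"
  fit <- fit_cox(data, spec)
  est <- dplyr::bind_cols(
    tidy(fit),
    tidy(fit, exponentiate = TRUE)[, c("estimate", "conf.low",
                                       "conf.high")] |>
      stats::setNames(c("hazard_ratio", "hr.conf.low", "hr.conf.high"))
  )
  sensitivity <- list()
  for (ex in exclude) {
    keep <- setdiff(studies, ex)
    if (length(keep) < 2 || length(keep) == length(studies)) next
    sub <- data[data$study %in% keep, , drop = FALSE]
    label <- paste0("without_", paste(ex, collapse = "_"))
    sensitivity[[label]] <- tidy(fit_cox(sub, spec),
                                 exponentiate = TRUE)
  }
  rt <- risk_table(data, times = times, window = window)
  if (is.null(stratum)) {
    stratum <- intersect(unique(fit$baseline$stratum), studies)[1]
  }
  if (is.null(patterns)) patterns <- default_risk_patterns()
  prof_rows <- list()
  cross_rows <- list()
  for (nm in names(patterns)) {
    pr <- try(
      pattern_risk_profile(fit, patterns[[nm]], stratum = stratum,
                           t_grid = t_grid, window = window,
                           threshold = threshold, conf = "none"),
      silent = TRUE
    )
    if (inherits(pr, "try-error")) next
    prof_rows[[nm]] <- dplyr::mutate(tibble::as_tibble(pr),
                                     pattern = nm, .before = 1)
    cross_rows[[nm]] <- tibble::tibble(
      pattern = nm,
      crossing_time = attr(pr, "crossing_time"),
      status = attr(pr, "crossing_status")
    )
  }
  structure(
    list(
      fit = fit,
      estimates = est,
      sensitivity = sensitivity,
      risk_table = rt,
      profiles = dplyr::bind_rows(prof_rows),
      crossings = dplyr::bind_rows(cross_rows),
      config = list(times = times, window = window,
                    threshold = threshold, stratum = stratum,
                    exclude = exclude)
    ),
    class = "szr_superpop_report"
  )
}

#' @export
print.szr_superpop_report <- function(x, ...) {
  cat("<szr_superpop_report> stratified fit on", x$fit$n, "subjects\n")
  print(x$estimates[, c("term", "hazard_ratio", "hr.conf.low",
                        "hr.conf.high")])
  invisible(x)
}

#' Default covariate patterns for risk profiles
#'
#' Aetiology x EEG x imaging x treatment combinations, holding seizures
#' not confined to sleep and no first-degree relative with epilepsy
#' fixed — the presentation used for per-group annual recurrence risks.
#'
#' @return A named list of patterns.
#' @export
default_risk_patterns <- function() {
  out <- list()
  for (ae in c("not_remote_symptomatic", "remote_symptomatic")) {
    for (ee in c("normal", "abnormal")) {
      for (im in c("normal", "abnormal")) {
        for (tr in c("delayed", "immediate")) {
          nm <- paste(
            ifelse(ae == "remote_symptomatic", "symptomatic",
                   "crypto_idio"),
            paste0("eeg_", ee), paste0("imaging_", im), tr, sep = "."
          )
          out[[nm]] <- list(aetiology = ae, eeg = ee, imaging = im,
                            treatment = tr, sleep_only = "no",
                            fdr_epilepsy = "no")
        }
      }
    }
  }
  out
}
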