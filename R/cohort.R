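#' Canonical cohort columns and category levels
#'
#' A cohort is an ordinary tibble with one row per subject and a fixed set
#' of columns: `subject_id`, `study`, `age_at_first_seizure` (years),
#' `sex`, `aetiology`, `fdr_epilepsy` (epilepsy in a first-degree
#' relative), `sleep_only` (seizures only while asleep), `eeg`, `imaging`
#' (CT/MRI result), `treatment` (policy), `time` (months from first to
#' second seizure or censoring) and `event` (1 = second seizure,
#' 0 = censored). Categorical columns are factors whose first level is the
#' reference category of the prognostic model (not remote symptomatic, no
#' relative, seizures not confined to sleep, normal EEG, normal imaging,
#' delayed treatment), so a hazard ratio above 1 always means greater risk
#' than baseline.
#'
#' A covariate that was never collected in a study (for example, seizures
#' while asleep in the FIRST trial) is represented as an all-`NA` column;
#' [covariate_available()] distinguishes that situation from ordinary
#' per-subject missingness.
#'
#' @return `cohort_levels()` returns the named list of canonical factor
#'   levels; `cohort_columns()` the canonical column names.
#' @export
cohort_levels <- function() {
  list(
    sex = c("male", "female"),
    aetiology = c("not_remote_symptomatic", "remote_symptomatic"),
    fdr_epilepsy = c("no", "yes"),
    sleep_only = c("no", "yes"),
    eeg = c("normal", "abnormal", "not_indicated"),
    imaging = c("normal", "abnormal", "not_indicated"),
    treatment = c("delayed", "immediate")
  )
}

#' @rdname cohort_levels
#' @export
cohort_columns <- function() {
  c("subject_id", "study", "age_at_first_seizure", "sex", "aetiology",
    "fdr_epilepsy", "sleep_only", "eeg", "imaging", "treatment",
    "time", "event")
}

#' Validate a cohort table
#'
#' Checks the contract every analysis function relies on: mandatory
#' columns present, unique subject ids, non-negative follow-up times,
#' 0/1 event indicators, and categorical values drawn from the canonical
#' coding. Categorical columns are coerced to factors with the canonical
#' level order; unknown values raise a warning and become `NA`.
#'
#' @param data A data frame of subject records.
#' @return A validated tibble with canonical column types.
#' @export
validate_cohort <- function(data) {
  mandatory <- c("study", "time", "event")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  if (!"subject_id" %in% names(out)) {
    out$subject_id <- sprintf("s%05d", seq_len(nrow(out)))
  }
  if (anyDuplicated(out$subject_id)) {
    abort("subject_id values must be unique within a cohort")
  }
  for (col in setdiff(cohort_columns(), names(out))) {
    out[[col]] <- switch(
      col,
      age_at_first_seizure = NA_real_,
      NA_character_
    )
  }
  out$study <- as.character(out$study)
  out$time <- as.numeric(out$time)
  out$event <- as.numeric(out$event)
  bad_time <- !is.na(out$time) & out$time < 0
  if (any(bad_time)) abort("follow-up times must be >= 0")
  if (!all(is.na(out$event) | out$event %in% c(0, 1))) {
    abort("event must be 0 (censored) or 1 (second seizure)")
  }
  lv <- cohort_levels()
  for (var in names(lv)) {
    x <- as.character(out[[var]])
    unknown <- !is.na(x) & !(x %in% lv[[var]])
    if (any(unknown)) {
      warn(paste0(
        "unknown ", var, " value(s) set to missing (rows ",
        paste(head(which(unknown), 10), collapse = ", "), "): ",
        paste(unique(x[unknown]), collapse = ", ")
      ))
      x[unknown] <- NA_character_
    }
    out[[var]] <- factor(x, levels = lv[[var]])
  }
  dplyr::select(out, dplyr::all_of(cohort_columns()), dplyr::everything())
}

#' Is a covariate available in a cohort?
#'
#' A covariate wholly absent from a study (never collected) appears as an
#' all-`NA` column; this is distinct from a column with sporadic missing
#' values.
#'
#' @param data A cohort tibble.
#' @param var Column name.
#' @return `TRUE` unless the column is missing or entirely `NA`.
#' @export
covariate_available <- function(data, var) {
  var %in% names(data) && !all(is.na(data[[var]]))
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, snake_case-headed cohort file and
#' validates it. An optional coding configuration (a named list, or a path
#' to a YAML file, of per-variable maps from source labels to canonical
#' levels) recodes arbitrary source labels; values not covered by the map
#' or the canonical coding become missing with a warning. Files recording
#' follow-up in days are converted to months (x 12/365.25).
#'
#' @param path CSV file path.
#' @param coding Optional coding configuration: named list
#'   `list(variable = c(source_label = "canonical_level", ...))`, or path
#'   to a YAML file with the same structure.
#' @param time_unit Unit of the `time` column in the file.
#' @return A validated cohort tibble; the source path and any unit
#'   conversion are recorded in the `"provenance"` attribute.
#' @export
read_cohort <- function(path, coding = NULL,
                        time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("study", "time", "event")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.character(coding) && length(coding) == 1) {
    coding <- yaml::read_yaml(coding)
  }
  if (!is.null(coding)) {
    for (var in intersect(names(coding), names(raw))) {
      map <- unlist(coding[[var]])
      x <- as.character(raw[[var]])
      hit <- x %in% names(map)
      x[hit] <- unname(map[x[hit]])
      raw[[var]] <- x
    }
  }
  if (time_unit == "days") raw$time <- raw$time * 12 / 365.25
  out <- validate_cohort(raw)
  attr(out, "provenance") <- paste0(
    "read from ", path,
    if (time_unit == "days") " (time converted days -> months)" else ""
  )
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: factors are written as their canonical
#' labels so that reading the file back reproduces the table.
#'
#' @param data A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- dplyr::mutate(
    data,
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Apply eligibility criteria
#'
#' Drops subjects younger than `min_age` at their first seizure (driving
#' regulations concern adults) and subjects with no outcome data (no
#' follow-up after the index seizure, i.e. missing `time` or `event`).
#' The per-reason exclusion counts are attached as the `"exclusion_log"`
#' attribute and available via [exclusion_log()].
#'
#' @param data A cohort tibble.
#' @param min_age Minimum age in years at first seizure (default 16).
#' @return The eligible subset, with an exclusion log attribute.
#' @export
filter_eligible <- function(data, min_age = 16) {
  no_outcome <- is.na(data$time) | is.na(data$event)
  too_young <- !no_outcome & !is.na(data$age_at_first_seizure) &
    data$age_at_first_seizure < min_age
  keep <- !no_outcome & !too_young
  log <- tibble::tibble(
    reason = c("no_outcome_data", "age"),
    n_excluded = c(sum(no_outcome), sum(too_young))
  )
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("no eligible subjects remain")
  attr(out, "exclusion_log") <- log
  out
}

#' @rdname filter_eligible
#' @param x A cohort returned by [filter_eligible()].
#' @export
exclusion_log <- function(x) attr(x, "exclusion_log")

#' Collapse EEG / imaging to two categories
#'
#' Some studies recorded every EEG and CT/MRI result as normal or abnormal
#' with no "not clinically indicated" option; validating against them
#' requires collapsing the three-level coding elsewhere to two levels.
#' Because a test that was never performed carries no normal/abnormal
#' information, `not_indicated` becomes missing rather than being folded
#' into either observed category; affected subjects then drop out of
#' complete-case model fits that use the variable.
#'
#' @param data A cohort tibble.
#' @param variables Which of `eeg`, `imaging` to collapse.
#' @return The cohort with two-level factors for the chosen variables.
#' @export
collapse_two_level <- function(data, variables = c("eeg", "imaging")) {
  bad <- setdiff(variables, c("eeg", "imaging"))
  if (length(bad) > 0) {
    abort(paste0("not collapsible (only eeg/imaging have a not_indicated ",
                 "level): ", paste(bad, collapse = ", ")))
  }
  for (var in variables) {
    if (!var %in% names(data)) abort(paste0("variable not present: ", var))
    x <- as.character(data[[var]])
    x[x == "not_indicated"] <- NA_character_
    data[[var]] <- factor(x, levels = c("normal", "abnormal"))
  }
  data
}

#' Demographic summary of a cohort
#'
#' Per-study counts and percentages for every categorical covariate
#' (including a `missing` row where applicable, with percentages over the
#' full column so each variable sums to 100 up to rounding), plus median
#' and inter-quartile range of age at first seizure.
#'
#' @param data A cohort tibble (one or more studies).
#' @return A long tibble with columns `study`, `variable`, `level`, `n`,
#'   `pct` (categorical rows) and `value` (age summary rows).
#' @export
summarize_cohort <- function(data) {
  vars <- names(cohort_levels())
  cat_rows <- purrr::map_dfr(vars, function(var) {
    data |>
      dplyr::mutate(
        level = forcats_na_level(.data[[var]]),
        variable = var
      ) |>
      dplyr::count(.data$study, .data$variable, .data$level, name = "n") |>
      dplyr::group_by(.data$study, .data$variable) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  })
  age_rows <- data |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(
      median = median(.data$age_at_first_seizure, na.rm = TRUE),
      q1 = quantile(.data$age_at_first_seizure, 0.25, na.rm = TRUE,
                    names = FALSE),
      q3 = quantile(.data$age_at_first_seizure, 0.75, na.rm = TRUE,
                    names = FALSE),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("median", "q1", "q3"),
                        names_to = "level", values_to = "value") |>
    dplyr::mutate(variable = "age_at_first_seizure")
  dplyr::bind_rows(cat_rows, age_rows) |>
    dplyr::arrange(.data$study, .data$variable)
}

# factor -> character with NA shown as the "missing" level
forcats_na_level <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  x
}

#' Demographics in a publication-style wide layout
#'
#' Pivots [summarize_cohort()] output to one column per study with
#' "n (pct)" entries, the layout used for demographic tables in seizure
#' prognosis reports.
#'
#' @param data A cohort tibble.
#' @return A wide tibble, one row per variable level.
#' @export
demographics_table <- function(data) {
  summarize_cohort(data) |>
    dplyr::mutate(
      cell = dplyr::if_else(
        is.na(.data$n),
        sprintf("%.1f", .data$value),
        sprintf("%d (%.0f)", .data$n, .data$pct)
      )
    ) |>
    dplyr::select("study", "variable", "level", "cell") |>
    tidyr::pivot_wider(names_from = "study", values_from = "cell")
}
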