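#' Define a Cox model specification
#'
#' A model specification lists the indicator terms of the proportional-
#' hazards model (one per non-reference category) and an optional
#' stratification variable. The default specification is the eight-term
#' seizure-recurrence model: remote symptomatic aetiology, first-degree
#' relative with epilepsy, seizures only while asleep, abnormal /
#' not-indicated EEG, abnormal / not-indicated CT/MRI, and immediate
#' treatment policy. Reference categories never appear as terms, so the
#' prognostic index of the reference pattern is exactly 0.
#'
#' @param terms A tibble with columns `variable` and `level`, one row per
#'   indicator term.
#' @param strata Optional name of a stratification column (usually
#'   `"study"`): strata share coefficients but have separate baseline
#'   hazards.
#' @return An object of class `szr_spec`.
#' @export
model_spec <- function(terms, strata = NULL) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("variable", "level") %in% names(terms)))
  terms$term <- paste(terms$variable, terms$level, sep = "_")
  if (anyDuplicated(terms$term)) abort("duplicated model terms")
  lv <- cohort_levels()
  ref <- vapply(lv, `[`, character(1), 1)
  is_ref <- !is.na(ref[terms$variable]) & terms$level == ref[terms$variable]
  if (any(is_ref)) {
    abort(paste0("reference levels cannot be model terms: ",
                 paste(terms$term[is_ref], collapse = ", ")))
  }
  structure(list(terms = terms, strata = strata), class = "szr_spec")
}

#' @rdname model_spec
#' @param two_level Use the two-level EEG/imaging coding (no
#'   `not_indicated` terms), for validation against studies where every
#'   subject had both investigations.
#' @param include_sleep Keep the seizures-only-while-asleep term; set
#'   `FALSE` for variable matching against a cohort that never recorded
#'   it.
#' @export
default_model_spec <- function(two_level = FALSE, include_sleep = TRUE,
                               strata = NULL) {
  terms <- tibble::tribble(
    ~variable, ~level,
    "aetiology", "remote_symptomatic",
    "fdr_epilepsy", "yes",
    "sleep_only", "yes",
    "eeg", "abnormal",
    "eeg", "not_indicated",
    "imaging", "abnormal",
    "imaging", "not_indicated",
    "treatment", "immediate"
  )
  if (two_level) terms <- terms[terms$level != "not_indicated", ]
  if (!include_sleep) terms <- terms[terms$variable != "sleep_only", ]
  model_spec(terms, strata = strata)
}

#' Drop one covariate from a specification
#'
#' Removes every indicator term belonging to `variable` (used by the
#' variable-matching strategy for a covariate absent from a validation
#' dataset).
#'
#' @param spec A `szr_spec`.
#' @param variable Covariate whose terms are removed.
#' @return A reduced `szr_spec`.
#' @export
drop_spec_variable <- function(spec, variable) {
  stopifnot(inherits(spec, "szr_spec"))
  if (!variable %in% spec$terms$variable) {
    abort(paste0("variable not in specification: ", variable))
  }
  remaining <- spec$terms[spec$terms$variable != variable,
                          c("variable", "level")]
  if (nrow(remaining) == 0) {
    abort("removing this variable would leave an empty specification")
  }
  model_spec(remaining, strata = spec$strata)
}

#' @export
print.szr_spec <- function(x, ...) {
  cat("<szr_spec> ", nrow(x$terms), " terms",
      if (!is.null(x$strata)) paste0(", stratified by ", x$strata), "\n",
      sep = "")
  cat(paste0("  ", x$terms$term, collapse = "\n"), "\n")
  invisible(x)
}

# 0/1 indicator matrix for the spec terms; rows with any NA on a used
# covariate yield NA indicators (complete-case handling happens in fit)
spec_matrix <- function(data, spec) {
  X <- vapply(seq_len(nrow(spec$terms)), function(i) {
    var <- spec$terms$variable[i]
    lev <- spec$terms$level[i]
    as.numeric(as.character(data[[var]]) == lev)
  }, numeric(nrow(data)))
  X <- matrix(X, nrow = nrow(data))
  colnames(X) <- spec$terms$term
  X
}
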