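#' Variable matching for a wholly missing covariate
#'
#' When a covariate was never collected in a validation dataset, the
#' simplest remedy is to refit the model on the development cohort with
#' that covariate removed, and validate the reduced model. Some
#' discriminative information is necessarily lost.
#'
#' @param dev_data Development cohort tibble.
#' @param spec Full `szr_spec`.
#' @param missing_var Covariate absent from the validation dataset.
#' @param ties Passed to [fit_cox()].
#' @return A list: `spec` (reduced) and `fit` (`szr_cox` of the reduced
#'   model on the development cohort).
#' @export
variable_matching <- function(dev_data, spec, missing_var,
                              ties = "efron") {
  reduced <- drop_spec_variable(spec, missing_var)
  list(spec = reduced, fit = fit_cox(dev_data, reduced, ties = ties))
}

#' Impute by random selection with replacement
#'
#' Each missing entry is filled by drawing, with replacement, from the
#' observed values of the equivalent variable in the development
#' dataset; the imputed column reproduces the development marginal in
#' expectation.
#'
#' @param dev_values Observed development column (factor or character;
#'   `NA`s are dropped).
#' @param n Number of entries to impute.
#' @param seed Integer seed.
#' @return A factor of length `n` with the development column's levels.
#' @export
impute_random_selection <- function(dev_values, n, seed = 1) {
  lev <- if (is.factor(dev_values)) levels(dev_values) else
    sort(unique(as.character(dev_values[!is.na(dev_values)])))
  pool <- as.character(dev_values[!is.na(dev_values)])
  if (length(pool) == 0) abort("development column has no observed values")
  withr::with_seed(seed, {
    factor(sample(pool, n, replace = TRUE), levels = lev)
  })
}

#' Impute from an estimated proportion
#'
#' Single imputation via the summary statistic of the development
#' column: each entry is an independent Bernoulli draw with the supplied
#' probability of the non-reference (`yes`) level.
#'
#' @param dev_proportion Probability of `levels[2]` in the development
#'   data.
#' @param n Number of entries to impute.
#' @param seed Integer seed.
#' @param levels The two category labels (reference first).
#' @return A factor of length `n`.
#' @export
impute_proportion <- function(dev_proportion, n, seed = 1,
                              levels = c("no", "yes")) {
  if (dev_proportion < 0 || dev_proportion > 1) {
    abort("dev_proportion must lie in [0, 1]")
  }
  withr::with_seed(seed, {
    factor(levels[1 + rbinom(n, 1, dev_proportion)], levels = levels)
  })
}

#' Hot-deck imputation from similar development subjects
#'
#' Each recipient's missing value is drawn uniformly from the donors —
#' development subjects that match the recipient exactly on all matching
#' variables. When a recipient has no exact donor, matching variables
#' are dropped one at a time from the end of the priority list until
#' donors exist (falling back to the whole observed column), and the
#' relaxation is recorded in the `"hot_deck_log"` attribute.
#'
#' @param dev_data Development cohort tibble.
#' @param val_data Validation cohort tibble (recipients).
#' @param missing_var Covariate to impute.
#' @param matching_vars Matching variables in priority order.
#' @param seed Integer seed.
#' @return A factor of length `nrow(val_data)`.
#' @export
impute_hot_deck <- function(dev_data, val_data, missing_var,
                            matching_vars = c("aetiology", "eeg",
                                              "treatment",
                                              "fdr_epilepsy"),
                            seed = 1) {
  if (!covariate_available(dev_data, missing_var)) {
    abort(paste0("development column entirely missing: ", missing_var))
  }
  donors_all <- dev_data[!is.na(dev_data[[missing_var]]), , drop = FALSE]
  lev <- levels(factor(dev_data[[missing_var]]))
  n <- nrow(val_data)
  donor_vals <- as.character(donors_all[[missing_var]])
  key_of <- function(d, vars) {
    if (length(vars) == 0) return(rep(".pool", nrow(d)))
    do.call(paste, c(lapply(vars, function(v) as.character(d[[v]])),
                     sep = "\r"))
  }
  # donor pools for the full matching key and each relaxation of it
  prefixes <- lapply(rev(seq(0, length(matching_vars))), function(k) {
    matching_vars[seq_len(k)]
  })
  pools <- lapply(prefixes, function(vars) {
    split(donor_vals, key_of(donors_all, vars))
  })
  recipient_keys <- lapply(prefixes, function(vars) key_of(val_data, vars))
  log_lines <- character(0)
  withr::with_seed(seed, {
    out <- character(n)
    for (i in seq_len(n)) {
      for (p in seq_along(prefixes)) {
        vars <- prefixes[[p]]
        pool <- pools[[p]][[recipient_keys[[p]][i]]]
        if (!is.null(pool) && length(pool) > 0) {
          if (p > 1) {
            log_lines <- c(log_lines, paste0(
              "recipient ", i, ": matched on ",
              if (length(vars) == 0) "nothing (whole-column draw)"
              else paste(vars, collapse = "+")))
          }
          out[i] <- pool[sample.int(length(pool), 1)]
          break
        }
      }
    }
    structure(factor(out, levels = lev), hot_deck_log = log_lines)
  })
}

#' Impute by averaging repeated random selections
#'
#' Draws `M` independent random-selection columns and averages them per
#' entry; for a binary covariate the average is resolved by majority
#' vote at 0.5, with exact ties broken toward the development majority
#' level. All `M` draws and the per-entry mean are retained.
#'
#' @param dev_values Observed development column (two levels).
#' @param n Number of entries to impute.
#' @param M Number of repeated draws (at least 2; default 10).
#' @param seed Integer seed.
#' @return A list: `imputed` (factor of length `n`), `mean` (per-entry
#'   mean of the binary draws), `draws` (n x M factor matrix as
#'   character).
#' @export
impute_multiple_random <- function(dev_values, n, M = 10, seed = 1) {
  if (M < 2) abort("M must be >= 2")
  lev <- if (is.factor(dev_values)) levels(dev_values) else
    sort(unique(as.character(dev_values[!is.na(dev_values)])))
  if (length(lev) != 2) abort("multiple random selection expects a binary covariate")
  pool <- as.character(dev_values[!is.na(dev_values)])
  majority <- lev[1 + (mean(pool == lev[2]) > 0.5)]
  withr::with_seed(seed, {
    draws <- matrix(sample(pool, n * M, replace = TRUE), nrow = n)
    bin <- draws == lev[2]
    m <- rowMeans(bin)
    imputed <- ifelse(m > 0.5, lev[2], ifelse(m < 0.5, lev[1], majority))
    list(
      imputed = factor(imputed, levels = lev),
      mean = m,
      draws = draws
    )
  })
}

#' Apply one of the five missing-covariate strategies to a cohort
#'
#' Convenience wrapper used by the validation pipeline: returns the
#' validation cohort with the missing covariate filled in by the chosen
#' imputation method (for `variable_matching` the cohort is returned
#' unchanged — that method instead reduces the model).
#'
#' @param dev_data Development cohort tibble.
#' @param val_data Validation cohort tibble.
#' @param missing_var Covariate to handle (default `sleep_only`).
#' @param method One of `variable_matching`, `random_selection`,
#'   `proportion`, `hot_deck`, `multiple_random`.
#' @param M Draws for `multiple_random`.
#' @param matching_vars Matching priority for `hot_deck`.
#' @param seed Integer seed.
#' @return `val_data`, imputed where applicable, with a `"method"`
#'   attribute.
#' @export
impute_missing_covariate <- function(dev_data, val_data,
                                     missing_var = "sleep_only",
                                     method = c("hot_deck",
                                                "variable_matching",
                                                "random_selection",
                                                "proportion",
                                                "multiple_random"),
                                     M = 10,
                                     matching_vars = c("aetiology", "eeg",
                                                       "treatment",
                                                       "fdr_epilepsy"),
                                     seed = 1) {
  method <- match.arg(method)
  dev_col <- dev_data[[missing_var]]
  n <- nrow(val_data)
  col <- switch(
    method,
    variable_matching = val_data[[missing_var]],
    random_selection = impute_random_selection(dev_col, n, seed),
    proportion = impute_proportion(
      mean(as.character(dev_col[!is.na(dev_col)]) ==
             levels(factor(dev_col))[2]),
      n, seed, levels = levels(factor(dev_col))
    ),
    hot_deck = impute_hot_deck(dev_data, val_data, missing_var,
                               matching_vars, seed),
    multiple_random = impute_multiple_random(dev_col, n, M, seed)$imputed
  )
  val_data[[missing_var]] <- factor(as.character(col),
                                    levels = cohort_levels()[[missing_var]])
  attr(val_data, "method") <- method
  val_data
}
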