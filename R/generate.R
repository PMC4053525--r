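#' Generate a synthetic cohort from a study profile
#'
#' Draws covariates independently from the profile's marginals, event
#' times from an exponential baseline whose hazard is multiplied by
#' `exp(linear predictor)` with the profile's generating log hazard
#' ratios, and censoring times from uniform study entry over an accrual
#' period before an administrative study end plus independent exponential
#' dropout. Missingness is applied last: covariates listed as unavailable
#' in the profile are masked for every subject (after contributing to the
#' true hazard) and per-covariate missing fractions are applied at
#' random. Generation is deterministic given `(profile, n, seed)`.
#'
#' The generating truth — each subject's latent linear predictor and
#' uncensored event time — is kept in the `.true_lp` and `.true_time`
#' columns so that parameter-recovery checks are self-contained; analysis
#' functions ignore these columns.
#'
#' @param profile An `szr_profile`, e.g. one element of
#'   [study_profiles()].
#' @param n Number of subjects (default the profile's published size).
#' @param seed Integer seed.
#' @return A validated cohort tibble with truth columns.
#' @export
generate_cohort <- function(profile, n = profile$n_default, seed = 1) {
  stopifnot(inherits(profile, "szr_profile"))
  if (n < 1) abort("n must be >= 1")
  withr::with_seed(seed, {
    draw <- function(var) {
      p <- profile$marginals[[var]]
      factor(sample(names(p), n, replace = TRUE, prob = p),
             levels = cohort_levels()[[var]])
    }
    dat <- tibble::tibble(
      subject_id = sprintf("%s-%06d", profile$name, seq_len(n)),
      study = profile$name,
      age_at_first_seizure = pmax(
        16, stats::rlnorm(n, profile$age["meanlog"], profile$age["sdlog"])
      ),
      sex = draw("sex"),
      aetiology = draw("aetiology"),
      fdr_epilepsy = draw("fdr_epilepsy"),
      sleep_only = draw("sleep_only"),
      eeg = draw("eeg"),
      imaging = draw("imaging"),
      treatment = draw("treatment")
    )
    spec <- default_model_spec()
    lp <- drop(spec_matrix(dat, spec) %*%
                 profile$log_hr[spec$terms$term])
    true_time <- rexp(n, rate = profile$baseline_rate * exp(lp))
    cens <- profile$censoring
    entry <- runif(n, 0, cens$accrual)
    c_admin <- cens$window - entry
    c_drop <- if (cens$dropout_rate > 0) {
      rexp(n, cens$dropout_rate)
    } else {
      rep(Inf, n)
    }
    c_all <- pmin(c_admin, c_drop)
    dat$time <- pmin(true_time, c_all)
    dat$event <- as.numeric(true_time <= c_all)
    for (var in profile$unavailable) {
      dat[[var]][] <- NA
    }
    mf <- profile$missing_fractions
    for (var in names(mf)) {
      hit <- runif(n) < mf[[var]]
      dat[[var]][hit] <- NA
    }
    dat$.true_lp <- lp
    dat$.true_time <- true_time
    validate_cohort(dat)
  })
}

#' Generate a pooled multi-study cohort
#'
#' Concatenates per-study generations with distinct study labels and
#' study-specific baseline hazards, so that a Cox model stratified by
#' study (shared coefficients, separate baselines) is the correctly
#' specified model for the pooled data. Per-study seeds are derived
#' deterministically from the master seed (`seed + k - 1` for the k-th
#' profile), so a single-profile pool reproduces [generate_cohort()]
#' exactly.
#'
#' @param profiles A list of `szr_profile` objects with distinct names.
#' @param n_per_study Subject counts, recycled to the number of profiles;
#'   default each profile's published size.
#' @param seed Master integer seed.
#' @return A validated pooled cohort tibble with truth columns.
#' @export
generate_superpopulation <- function(profiles, n_per_study = NULL,
                                     seed = 1) {
  nm <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nm)) abort("duplicate study names in profiles")
  if (is.null(n_per_study)) {
    n_per_study <- vapply(profiles, function(p) p$n_default, numeric(1))
  }
  n_per_study <- rep_len(n_per_study, length(profiles))
  purrr::map_dfr(seq_along(profiles), function(k) {
    generate_cohort(profiles[[k]], n = n_per_study[k], seed = seed + k - 1)
  })
}
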