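test_that("product-limit estimates match hand computation", {
  # no events: survival stays at 1 with zero variance
  km0 <- km_estimate(c(2, 4, 6, 8, 10), rep(0, 5))
  expect_true(all(km0$surv == 1))
  expect_true(all(km0$greenwood == 0))

  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  at <- km_at(km, c(1, 2, 4))
  expect_equal(at$surv, c(3 / 4, 1 / 2, 0))

  # a tied pair of events leaves half the risk set
  km2 <- km_estimate(c(2, 2, 5, 7), c(1, 1, 0, 0))
  expect_equal(km_at(km2, 2)$surv, 1 / 2)

  expect_error(km_estimate(numeric(0), numeric(0)), "no subjects")
})

test_that("KM without censoring equals the empirical survival function", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      t <- sample(1:6, n, replace = TRUE)
      km <- km_estimate(t, rep(1, n))
      for (tt in unique(t)) {
        expect_equal(km_at(km, tt)$surv, mean(t > tt))
      }
    }
  })
})

test_that("numbers at risk count subjects still under follow-up", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(km_at(km, c(0, 1, 2.5, 4))$n_risk, c(4, 4, 2, 1))
})

test_that("Cox fit matches the closed-form score-equation solution", {
  withr::with_seed(23, {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    t <- round(rexp(n, 0.1 * exp(0.7 * x)), 6)  # continuous, no ties
    e <- rep(1, n)
    co <- mini_cohort(time = t, event = e,
                      treatment = ifelse(x == 1, "immediate",
                                         "delayed"))
    spec <- model_spec(tibble::tibble(variable = "treatment",
                                      level = "immediate"))
    fit <- fit_cox(co, spec)
    expect_equal(unname(fit$coefficients), oracle_cox_beta(t, e, x),
                 tolerance = 1e-8)
  })
})

test_that("null data give null coefficients", {
  p <- study_profiles()$MESS
  p$log_hr[] <- 0
  co <- generate_cohort(p, n = 5000, seed = 57)
  est <- tidy(fit_cox(co))
  expect_true(all(abs(est$estimate) < 3 * est$std.error))
})

test_that("separation is reported as an error naming the term", {
  co <- mini_cohort(time = c(1, 2, 3, 10, 11, 12),
                    event = rep(1, 6),
                    eeg = c(rep("abnormal", 3), rep("normal", 3)))
  spec <- model_spec(tibble::tibble(variable = "eeg",
                                    level = "abnormal"))
  suppressWarnings(expect_error(fit_cox(co, spec), "eeg_abnormal"))
})

test_that("stratified estimates ignore per-stratum time rescaling", {
  ps <- study_profiles()
  pool <- generate_superpopulation(list(ps$MESS, ps$NGPSE),
                                   n_per_study = 800, seed = 19)
  spec <- default_model_spec(strata = "study")
  f1 <- fit_cox(pool, spec)
  scaled <- pool
  scaled$time[scaled$study == "NGPSE"] <-
    scaled$time[scaled$study == "NGPSE"] * 7
  f2 <- fit_cox(scaled, spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("prognostic index is the linear predictor with reference 0", {
  co <- generate_cohort(study_profiles()$MESS, n = 500, seed = 3)
  fit <- fit_cox(co)
  ref <- mini_cohort(time = 1, event = 1)
  expect_equal(prognostic_index(ref, fit)$.pi, 0)
  expect_equal(pattern_lp(fit, list()), 0)
  expect_equal(pattern_lp(fit, list(sleep_only = "yes")),
               unname(fit$coefficients["sleep_only_yes"]))
  # additivity across single-term patterns
  expect_equal(
    pattern_lp(fit, list(sleep_only = "yes", eeg = "abnormal")),
    pattern_lp(fit, list(sleep_only = "yes")) +
      pattern_lp(fit, list(eeg = "abnormal"))
  )
  expect_error(pattern_lp(fit, list(eeg = "odd")), "invalid pattern")
})

test_that("baseline survivor interpolates linearly between event times", {
  s <- survfn(time = c(0, 2, 4), surv = c(1, 0.9, 0.8))
  expect_equal(eval_survfn(s, 0), 1, ignore_attr = TRUE)
  expect_equal(eval_survfn(s, 3), 0.85, ignore_attr = TRUE)
  v <- eval_survfn(s, c(4, 10))
  expect_equal(as.numeric(v), c(0.8, 0.8))
  expect_equal(attr(v, "extrapolated"), c(FALSE, TRUE))
})

test_that("predicted survival follows S0^exp(lp)", {
  co <- generate_cohort(study_profiles()$MESS, n = 3000, seed = 71)
  fit <- fit_cox(co)
  s0 <- baseline_survivor(fit)
  tt <- c(3, 9, 18)
  expect_equal(as.numeric(predict_survivor(fit, list(), tt)),
               as.numeric(eval_survfn(s0, tt)))
  lo <- predict_survivor(fit, list(), tt)
  hi <- predict_survivor(fit, list(eeg = "abnormal",
                                   aetiology = "remote_symptomatic"),
                         tt)
  expect_true(all(hi < lo))              # higher risk, lower survival
  expect_true(all(diff(as.numeric(hi)) < 0))  # non-increasing in t
  expect_error(baseline_survivor(fit, "nowhere"), "unknown stratum")
})

test_that("predictions match the exponential closed form", {
  # single binary covariate, known exponential truth
  p <- study_profiles()$MESS
  p$log_hr[] <- 0
  p$log_hr["treatment_immediate"] <- log(2)
  p$censoring <- list(window = 400, accrual = 1, dropout_rate = 0)
  co <- generate_cohort(p, n = 12000, seed = 83)
  spec <- model_spec(tibble::tibble(variable = "treatment",
                                    level = "immediate"))
  fit <- fit_cox(co, spec)
  lambda <- p$baseline_rate
  tt <- c(6, 12, 24)
  pred_ref <- as.numeric(predict_survivor(fit, list(), tt))
  expect_equal(pred_ref, exp(-lambda * tt), tolerance = 0.03)
  pred_trt <- as.numeric(
    predict_survivor(fit, list(treatment = "immediate"), tt)
  )
  expect_equal(pred_trt, exp(-lambda * 2 * tt), tolerance = 0.05)
})
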