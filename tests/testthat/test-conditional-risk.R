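# hand-checkable eight-subject fixture used throughout:
# times 2,4,4,6,8,10,12,14; events 1,1,0,1,0,1,1,0
fix_times <- c(2, 4, 4, 6, 8, 10, 12, 14)
fix_events <- c(1, 1, 0, 1, 0, 1, 1, 0)

test_that("conditional survival is a ratio of survivor values", {
  s <- survfn(time = c(0, 6, 18, 30), surv = c(1, 0.8, 0.55, 0.4))
  expect_equal(conditional_survivor(s, 6, 6), 1)
  expect_equal(conditional_survivor(s, 6, 18), 0.55 / 0.8)
  # S(t1) * conditional = S(t2) on any survivor function
  expect_equal(
    as.numeric(eval_survfn(s, 7)) * conditional_survivor(s, 7, 20),
    as.numeric(eval_survfn(s, 20))
  )
  # exponential memorylessness, via a plain function
  sexp <- function(t) exp(-0.05 * t)
  expect_equal(conditional_survivor(sexp, 6, 18), exp(-0.05 * 12))
  expect_error(conditional_survivor(s, 10, 5), "t1 <= t2")
  szero <- function(t) ifelse(t < 1, 1, 0)
  expect_error(conditional_survivor(szero, 2, 3), "undefined")
})

test_that("forward risk on the KM fixture matches hand computation", {
  km <- km_estimate(fix_times, fix_events)
  fr <- forward_risk(km, 0, window = 12)
  expect_equal(fr$risk, 1 - 1 / 5)
  # windowed variance anchored at 0 is the plain Greenwood accumulator
  g12 <- 1 / 56 + 1 / 42 + 1 / 20 + 1 / 6 + 1 / 2
  ratio <- 1 / 5
  z <- qnorm(0.975)
  expect_equal(fr$conf.low, 1 - min(ratio * exp(z * sqrt(g12)), 1))
  expect_equal(fr$conf.high, 1 - ratio * exp(-z * sqrt(g12)))

  fr2 <- forward_risk(km, 2, window = 10)
  expect_equal(fr2$risk, 1 - (1 / 5) / (7 / 8))
  # conditional Greenwood: only the events inside (2, 12] contribute
  expect_equal(
    forward_risk(km, 2, window = 10)$risk,
    1 - conditional_survivor(
      function(t) km_at(km, t)$surv, 2, 12
    )
  )
  expect_error(forward_risk(km, 4, window = 12), "last observed")
})

test_that("no events in the window give zero risk with a point CI", {
  km <- km_estimate(c(1, 2, 9, 10), c(1, 1, 0, 0))
  fr <- forward_risk(km, 3, window = 6)
  expect_equal(fr$risk, 0)
  expect_equal(fr$conf.low, 0)
  expect_equal(fr$conf.high, 0)
})

test_that("exponential data give a flat forward-risk profile", {
  lambda <- 0.03
  withr::with_seed(501, {
    t <- rexp(10000, lambda)
    km <- km_estimate(pmin(t, 60), as.numeric(t <= 60))
  })
  fr <- forward_risk(km, c(0, 6, 12, 24), window = 12)
  expect_equal(fr$risk, rep(1 - exp(-12 * lambda), 4), tolerance = 0.05)
  expect_lt(diff(range(fr$risk)), 0.04)
  expect_true(all(fr$risk >= 0 & fr$risk <= 1))
})

test_that("the per-arm risk table reflects a protective treatment", {
  ps <- study_profiles("superpopulation")
  pool <- generate_superpopulation(ps, n_per_study = 2500, seed = 11)
  rt <- risk_table(pool, times = c(6, 12))
  expect_setequal(rt$treatment, c("delayed", "immediate"))
  imm <- rt[rt$treatment == "immediate", ]
  del <- rt[rt$treatment == "delayed", ]
  expect_true(all(imm$risk < del$risk))
  expect_true(all(rt$n_risk > 0))
  expect_match(rt$label[1], "^\\d+ \\(\\d+ to \\d+\\)$")
})

test_that("pattern profiles follow the model and order by risk", {
  p <- study_profiles()$MESS
  co <- generate_cohort(p, n = 8000, seed = 61)
  fit <- fit_cox(co)
  prof_ref <- pattern_risk_profile(fit, list(),
                                   t_grid = seq(0, 12, 2))
  s0 <- baseline_survivor(fit)
  expect_equal(prof_ref$risk,
               forward_risk(s0, prof_ref$t, window = 12)$risk)
  prof_hi <- pattern_risk_profile(fit, list(eeg = "abnormal"),
                                  t_grid = seq(0, 12, 2))
  expect_true(all(prof_hi$risk > prof_ref$risk))
  # exponential generating truth: risk close to 1 - exp(-12 lambda e^lp)
  lam <- p$baseline_rate
  expect_lt(max(abs(prof_ref$risk - (1 - exp(-12 * lam)))), 0.04)
})

test_that("bootstrap bands cover the point profile", {
  co <- generate_cohort(study_profiles()$MESS, n = 1200, seed = 71)
  fit <- fit_cox(co)
  prof <- pattern_risk_profile(fit, list(eeg = "abnormal"),
                               t_grid = c(0, 6, 12), conf = "bootstrap",
                               B = 25, seed = 3, data = co)
  expect_true(all(c("conf.low", "conf.high") %in% names(prof)))
  expect_true(all(prof$conf.low <= prof$conf.high))
  expect_true(all(prof$conf.low >= 0 & prof$conf.high <= 1))
})

test_that("threshold crossing is located and labelled", {
  # flat profiles never cross or are already below
  expect_equal(threshold_time(function(t) 0.15, 0.2,
                              c(0, 24))$status, "already_below")
  expect_equal(threshold_time(function(t) 0.25, 0.2,
                              c(0, 24))$status, "never_below")

  # piecewise-linear survivor built to cross 20% at exactly 7.4 months
  s <- survfn(time = c(0, 7.4, 19.4, 60),
              surv = c(1, 0.8, 0.64, 0.5588))
  risk_fn <- function(t) 1 - conditional_survivor(s, t, t + 12)
  cross <- threshold_time(risk_fn, 0.2, c(0, 40))
  expect_equal(cross$time, 7.4)
  expect_equal(cross$status, "crossed")

  # relaxing the threshold can only move the crossing earlier
  relaxed <- threshold_time(risk_fn, 0.25, c(0, 40))
  expect_lte(relaxed$time, cross$time)
})

test_that("treatment lowers the model-based six-month forward risk", {
  ps <- study_profiles("superpopulation")
  ok <- 0
  for (seed in 1:5) {
    pool <- generate_superpopulation(ps[c("MESS", "NGPSE", "WA")],
                                     n_per_study = 700, seed = seed)
    fit <- fit_cox(pool, default_model_spec(strata = "study"))
    r_del <- forward_risk(pattern_survfn(fit, list(), "MESS"), 6)$risk
    r_imm <- forward_risk(
      pattern_survfn(fit, list(treatment = "immediate"), "MESS"), 6
    )$risk
    ok <- ok + (r_imm < r_del)
  }
  expect_gte(ok, 4)
})
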