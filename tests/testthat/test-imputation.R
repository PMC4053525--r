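test_that("variable matching reduces the specification and refits", {
  co <- generate_cohort(study_profiles()$MESS, n = 2000, seed = 5)
  vm <- variable_matching(co, default_model_spec(), "sleep_only")
  expect_equal(nrow(vm$spec$terms), 7)
  expect_false("sleep_only_yes" %in% names(vm$fit$coefficients))
  one_var <- model_spec(tibble::tibble(variable = "sleep_only",
                                       level = "yes"))
  expect_error(variable_matching(co, one_var, "sleep_only"), "empty")
})

test_that("variable matching loses little when the dropped covariate is
           independent, but loses discrimination on average", {
  co <- generate_cohort(study_profiles()$MESS, n = 8000, seed = 6)
  full <- fit_cox(co)
  vm <- variable_matching(co, default_model_spec(), "sleep_only")
  shared <- names(vm$fit$coefficients)
  # covariates are generated independently: remaining effects shift
  # only mildly when sleep is dropped
  expect_equal(vm$fit$coefficients[shared],
               full$coefficients[shared], tolerance = 0.15)
  c_full <- {
    s <- prognostic_index(co, full)
    harrell_c(s$time, s$event, s$.pi)$c
  }
  c_red <- {
    s <- prognostic_index(co, vm$fit)
    harrell_c(s$time, s$event, s$.pi)$c
  }
  expect_lte(c_red, c_full + 0.005)
})

test_that("random selection reproduces the development column", {
  expect_equal(
    as.character(impute_random_selection(factor(rep("no", 5),
                                                levels = c("no", "yes")),
                                         4, seed = 1)),
    rep("no", 4)
  )
  dev <- factor(c(rep("yes", 18), rep("no", 82)),
                levels = c("no", "yes"))
  imp <- impute_random_selection(dev, 10000, seed = 2)
  expect_lt(abs(mean(imp == "yes") - 0.18), 0.015)
  expect_identical(impute_random_selection(dev, 100, seed = 9),
                   impute_random_selection(dev, 100, seed = 9))
})

test_that("proportion-based imputation follows the Bernoulli rate", {
  expect_true(all(impute_proportion(0, 50, seed = 1) == "no"))
  expect_true(all(impute_proportion(1, 50, seed = 1) == "yes"))
  imp <- impute_proportion(0.18, 10000, seed = 3)
  # binomial 99% interval around 0.18 at n = 10,000
  expect_lt(abs(mean(imp == "yes") - 0.18),
            2.58 * sqrt(0.18 * 0.82 / 10000))
  expect_error(impute_proportion(1.2, 5), "0, 1")
})

test_that("random-selection and proportion imputation share a marginal", {
  dev <- factor(c(rep("yes", 18), rep("no", 82)),
                levels = c("no", "yes"))
  a <- mean(impute_random_selection(dev, 20000, seed = 4) == "yes")
  b <- mean(impute_proportion(0.18, 20000, seed = 4) == "yes")
  expect_equal(a, b, tolerance = 0.015)
})

test_that("hot deck draws from exactly matching donors", {
  dev <- mini_cohort(
    time = 1:4, event = 1,
    aetiology = c("remote_symptomatic", "not_remote_symptomatic",
                  "not_remote_symptomatic", "remote_symptomatic"),
    sleep_only = c("yes", "no", "no", "yes")
  )
  val <- mini_cohort(time = 1, event = 1,
                     aetiology = "remote_symptomatic")
  # both remote-symptomatic donors say yes: deterministic
  imp <- impute_hot_deck(dev, val, "sleep_only",
                         matching_vars = "aetiology", seed = 1)
  expect_equal(as.character(imp), "yes")

  # recipient matching no donor on any variable: whole-column fallback
  val2 <- mini_cohort(time = 1, event = 1, aetiology = NA)
  imp2 <- impute_hot_deck(dev, val2, "sleep_only",
                          matching_vars = "aetiology", seed = 1)
  expect_false(is.na(imp2))
  expect_match(attr(imp2, "hot_deck_log"), "whole-column")

  dev_empty <- dev
  dev_empty$sleep_only[] <- NA
  expect_error(impute_hot_deck(dev_empty, val, "sleep_only"),
               "entirely missing")
})

test_that("hot deck preserves the conditional distribution of donors", {
  withr::with_seed(411, {
    n <- 6000
    trt <- sample(c("immediate", "delayed"), n, replace = TRUE)
    sleep <- ifelse(
      runif(n) < ifelse(trt == "immediate", 0.10, 0.40), "yes", "no"
    )
    dev <- mini_cohort(time = runif(n, 1, 50),
                       event = rbinom(n, 1, 0.5),
                       treatment = trt, sleep_only = sleep)
    val <- mini_cohort(time = runif(n, 1, 50),
                       event = rbinom(n, 1, 0.5),
                       treatment = sample(c("immediate", "delayed"), n,
                                          replace = TRUE))
    val$sleep_only[] <- NA
    imp <- impute_hot_deck(dev, val, "sleep_only",
                           matching_vars = "treatment", seed = 2)
    p_imm <- mean(imp[val$treatment == "immediate"] == "yes")
    p_del <- mean(imp[val$treatment == "delayed"] == "yes")
    expect_lt(abs(p_imm - 0.10), 0.02)
    expect_lt(abs(p_del - 0.40), 0.03)
    # conditional distribution indistinguishable from the donors'
    tab <- rbind(
      table(dev$sleep_only[dev$treatment == "immediate"]),
      table(imp[val$treatment == "immediate"])
    )
    expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  })
})

test_that("averaged multiple random selection resolves by majority", {
  expect_error(impute_multiple_random(factor(c("no", "yes")), 5, M = 1),
               "M must be")
  all_yes <- factor(rep("yes", 10), levels = c("no", "yes"))
  out <- impute_multiple_random(all_yes, 6, M = 2, seed = 1)
  expect_true(all(out$imputed == "yes"))
  expect_equal(dim(out$draws), c(6, 2))

  dev <- factor(c(rep("yes", 18), rep("no", 82)),
                levels = c("no", "yes"))
  out2 <- impute_multiple_random(dev, 4000, M = 10, seed = 2)
  # per-entry means concentrate below 1/2 when the rate is 0.18
  expect_lt(mean(out2$imputed == "yes"), 0.05)
  # exact ties go to the development majority level ("no")
  ties <- out2$mean == 0.5
  if (any(ties)) expect_true(all(out2$imputed[ties] == "no"))
})

test_that("the cohort-level wrapper dispatches every method", {
  dev <- generate_cohort(study_profiles()$MESS, n = 1500, seed = 7)
  val <- generate_cohort(study_profiles()$FIRST, n = 800, seed = 8)
  for (m in c("random_selection", "proportion", "hot_deck",
              "multiple_random")) {
    out <- impute_missing_covariate(collapse_two_level(dev), val,
                                    method = m, seed = 3)
    expect_false(any(is.na(out$sleep_only)))
    expect_equal(attr(out, "method"), m)
  }
  vm <- impute_missing_covariate(dev, val, method = "variable_matching")
  expect_true(all(is.na(vm$sleep_only)))
})
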