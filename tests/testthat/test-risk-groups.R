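test_that("cut-points sit at the stated centiles of the index", {
  withr::with_seed(301, {
    g <- cox_cut_points(runif(20000))
    expect_equal(g$cut_points, c(0.16, 0.50, 0.84), tolerance = 0.02)
  })
  expect_error(cox_cut_points(rep(1, 50)), "distinct")
})

test_that("development-group shares follow the 16/34/34/16 split", {
  withr::with_seed(307, {
    pi_vals <- rnorm(100)                # distinct almost surely
    g <- cox_cut_points(pi_vals)
    grp <- assign_groups(pi_vals, g)
    expect_equal(unname(table(grp)["low"]), 16, tolerance = 1)
    expect_equal(unname(table(grp)["high"]), 16, tolerance = 1)
  })
})

test_that("assignment is monotone with the boundary in the lower group", {
  g <- structure(
    list(cut_points = c(1, 2, 3), centiles = c(16, 50, 84),
         labels = c("low", "moderately_low", "moderately_high", "high")),
    class = "szr_risk_grouping"
  )
  grp <- assign_groups(c(0.5, 1, 1.5, 2, 2.5, 3, 3.5), g)
  expect_equal(as.character(grp),
               c("low", "low", "moderately_low", "moderately_low",
                 "moderately_high", "moderately_high", "high"))
  x <- sort(rnorm(50))
  expect_true(!is.unsorted(assign_groups(x, g)))
})

test_that("random groups have near-unit hazard ratios", {
  withr::with_seed(311, {
    co <- generate_cohort(study_profiles()$MESS, n = 3000, seed = 97)
    co$risk_group <- factor(
      sample(c("low", "moderately_low", "moderately_high", "high"),
             nrow(co), replace = TRUE),
      levels = c("low", "moderately_low", "moderately_high", "high"),
      ordered = TRUE
    )
    hr <- group_hazard_ratios(co)
    expect_true(all(hr$conf.low < 1 & hr$conf.high > 1))
  })
})

test_that("transported groups show a monotone risk gradient", {
  co <- generate_cohort(study_profiles()$MESS, n = 6000, seed = 13)
  fit <- fit_cox(co)
  scored <- prognostic_index(co, fit)
  g <- cox_cut_points(scored$.pi[!is.na(scored$.pi)])
  grouped <- assign_groups(scored, g)
  hr <- group_hazard_ratios(grouped)
  ord <- c("moderately_low_vs_low", "moderately_high_vs_low",
           "high_vs_low")
  hrs <- hr$hazard_ratio[match(ord, hr$comparison)]
  expect_true(all(diff(hrs) > 0))
  expect_true(all(hrs > 1))

  km <- group_km(grouped)
  s12 <- km |>
    dplyr::filter(.data$time <= 12) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(s = min(.data$surv))
  s12 <- s12$s[match(c("low", "moderately_low", "moderately_high",
                       "high"), as.character(s12$group))]
  expect_true(all(diff(s12) < 0))        # ordered curves at 12 months
})

test_that("wider curve separation goes with larger hazard ratios", {
  mk <- function(scale, seed) {
    p <- study_profiles()$MESS
    p$log_hr <- p$log_hr * scale
    co <- generate_cohort(p, n = 6000, seed = seed)
    fit <- fit_cox(co)
    scored <- prognostic_index(co, fit)
    grouped <- assign_groups(
      scored, cox_cut_points(scored$.pi[!is.na(scored$.pi)])
    )
    group_hazard_ratios(grouped)
  }
  narrow <- mk(1, 23)
  wide <- mk(2.5, 23)
  hi <- function(tab) tab$hazard_ratio[tab$comparison == "high_vs_low"]
  expect_gt(hi(wide), hi(narrow))
})

test_that("a merged two-group split matches a two-sample Cox fit", {
  co <- generate_cohort(study_profiles()$MESS, n = 2000, seed = 29)
  fit <- fit_cox(co)
  scored <- prognostic_index(co, fit)
  med <- median(scored$.pi, na.rm = TRUE)
  co$risk_group <- factor(
    ifelse(scored$.pi <= med, "low", "high"),
    levels = c("low", "moderately_low", "moderately_high", "high"),
    ordered = TRUE
  )
  hr <- suppressWarnings(group_hazard_ratios(co))
  direct <- survival::coxph(
    survival::Surv(co$time, co$event) ~ I(scored$.pi > med)
  )
  expect_equal(hr$hazard_ratio[hr$comparison == "high_vs_low"],
               unname(exp(stats::coef(direct))), tolerance = 1e-8)
})

test_that("low-risk patients keep a low cumulative risk for longest", {
  co <- generate_cohort(study_profiles()$MESS, n = 6000, seed = 37)
  fit <- fit_cox(co)
  scored <- prognostic_index(co, fit)
  grouped <- assign_groups(
    scored, cox_cut_points(scored$.pi[!is.na(scored$.pi)])
  )
  km <- group_km(grouped)
  one <- function(g) {
    rows <- km[!is.na(km$group) & km$group == g, , drop = FALSE]
    km_time_below(rows, bound = 0.2)
  }
  expect_gt(one("low"), one("moderately_high"))
  expect_gt(one("low"), one("high"))
})
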