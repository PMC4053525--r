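# szvalid

Externally validating a prognostic model for seizure recurrence after a
first unprovoked seizure — and pooling it across cohorts.

## The problem

After a first unprovoked seizure, driving regulations in the UK and EU
allow a return to driving once the risk of another seizure in the next
12 months falls below 20%. That risk can be read off a Cox
proportional-hazards model of time from first to second seizure with six
clinical covariates: aetiology (remote symptomatic vs not), epilepsy in
a first-degree relative, seizures only while asleep, EEG result, CT/MRI
result, and treatment policy (immediate vs delayed antiepileptic drugs).
Before such a model informs regulation it must be shown to generalise
beyond the cohort it was developed on.

`szvalid` implements that external-validation study as a reusable,
tested pipeline for biostatisticians working with first-seizure cohorts:

- **Cohort handling** — CSV ingestion with a configurable coding map,
  eligibility filtering (age ≥ 16, outcome data present), two-level
  collapse of EEG/imaging, demographic summaries.
- **Synthetic cohorts** — a generator with four built-in study profiles
  (MESS, NGPSE, WA, FIRST) encoding published covariate marginals and
  hazard ratios as generating truth, study-specific censoring, and the
  FIRST pattern in which the sleep covariate was never collected. Real
  patient records are held by the original study groups; the generator
  makes every downstream stage testable without them.
- **Survival engine** — Cox fitting (Efron ties, optional stratification
  by study), prognostic index `PI = xβ̂`, Breslow-type baseline
  cumulative hazard, piecewise-linear baseline survivor
  `S(t|x) = S0(t)^exp(PI)`.
- **Validation** — Harrell's c-index `c = (concordant + ½·tied) /
  comparable pairs` with the ≤ 0.05 concordance-difference rule, and
  calibration of predicted against observed (Kaplan-Meier) survival by
  predicted-risk deciles.
- **Risk groups** — four groups cut at the 16th/50th/84th centiles of
  the development prognostic index (Cox's minimum-information-loss
  grouping), transported unchanged to validation cohorts, with
  per-group hazard ratios and KM curves.
- **Missing covariate** — the five strategies for a covariate absent
  from an entire validation dataset: variable matching, random
  selection with replacement, proportion-based single imputation, hot
  deck, and averaged multiple random selection.
- **Conditional risk** — forward risk `risk(t) = 1 − S(t+12)/S(t)` with
  confidence intervals from the Greenwood variance restricted to the
  window, per-arm risk tables, per-pattern risk profiles, and the time
  at which forward risk first falls to a threshold (20% by default).

## Worked example

```r
library(szvalid)

# four synthetic studies at their published sizes (620/274/847/305)
pool <- generate_superpopulation(study_profiles(), seed = 42)

report <- run_external_validation(pool, development = "MESS", seed = 42)
report$concordance
#> # A tibble: 10 × 9
#>    dataset                  method        c conf.low conf.high delta generalises
#>  1 MESS                     developm… 0.577    0.574     0.579 NA    NA
#>  2 NGPSE                    MESS      0.613    0.608     0.618  0.04 TRUE
#>  3 WA                       MESS      0.597    0.595     0.598  0.02 TRUE
#>  4 MESS: no sleep_only      developm… 0.569    0.566     0.572 NA    NA
#>  5 FIRST: variable_matching MESS: no… 0.584    0.579     0.589  0.02 TRUE
#>  6 MESS: with sleep_only    developm… 0.574    0.571     0.577 NA    NA
#>  7 FIRST: random_selection  MESS: wi… 0.589    0.584     0.594  0.02 TRUE
#>  8 FIRST: proportion        MESS: wi… 0.574    0.569     0.579  0    TRUE
#>  9 FIRST: hot_deck          MESS: wi… 0.571    0.566     0.575  0    TRUE
#> 10 FIRST: multiple_random   MESS: wi… 0.585    0.580     0.589  0.01 TRUE
```

Each row compares a validation cohort's c-index with its development
comparator (the full model, or — because FIRST never recorded the sleep
covariate — the reduced or two-level refit). `delta` is the difference
in concordance; a magnitude ≤ 0.05 is read as the model generalising.
Because the sleep covariate is absent from the synthetic FIRST cohort
exactly as in the real one, all five missing-covariate methods run, and
their c-indices agree closely.

Pooling all four cohorts and stratifying by study:

```r
sup <- run_superpopulation(pool)
sup$risk_table[, c("treatment", "time", "n_risk", "label")]
#> # A tibble: 8 × 4
#>   treatment  time n_risk label
#> 1 delayed       6    869 49 (45 to 52)
#> 2 delayed      12    598 47 (42 to 51)
#> 3 delayed      18    428 50 (45 to 54)
#> 4 delayed      24    308 50 (44 to 55)
#> 5 immediate     6    553 41 (37 to 45)
#> 6 immediate    12    409 37 (32 to 42)
#> 7 immediate    18    320 42 (36 to 47)
#> 8 immediate    24    247 41 (34 to 47)
```

`label` is the unadjusted risk of a seizure in the next 12 months (%,
with 95% CI) for someone still seizure free at `time` months — the
immediate-treatment arm sits below the delayed arm throughout, matching
the protective hazard ratio the cohorts were generated with. (Absolute
risk levels are a property of the synthetic generator's exponential
baseline, not estimates for real patients.) `sup$estimates` holds the
stratified hazard-ratio table, `sup$profiles` and `sup$crossings` the
per-pattern forward-risk curves and their 20%-threshold crossing times,
and `write_report_bundle(sup, "out/")` exports everything as CSV.

`autoplot()` methods draw KM curves, calibration plots and risk
profiles; `tidy()`/`glance()` give broom-style summaries of fits.

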