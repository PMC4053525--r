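---
title: "Methods: validating and pooling a seizure-recurrence prognostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating and pooling a seizure-recurrence prognostic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(szvalid)
```

## The model and its assumptions

The quantity of clinical interest is the risk of a second seizure in
the 12 months following some period of seizure freedom after a first
unprovoked seizure, because a 20% annual risk is the usual regulatory
bound for returning to drive. The underlying model is a Cox
proportional-hazards model for time from first to second seizure
(months), with indicator terms for remote symptomatic aetiology,
epilepsy in a first-degree relative, seizures occurring only while
asleep, abnormal or not-clinically-indicated EEG, abnormal or
not-clinically-indicated CT/MRI, and immediate (versus delayed)
antiepileptic treatment. Reference categories are fixed so that the
prognostic index $PI = x^\top\hat\beta$ is zero for the baseline
pattern and every hazard ratio above 1 means more risk than baseline.

The assumptions inherited from that model carry through the whole
pipeline: proportional hazards across covariate levels, no
interactions (none are fitted), and — when several cohorts are pooled —
shared covariate effects with study-specific baseline hazards
(stratified partial likelihood). Subjects missing a value on any
covariate used by a given fit are excluded from that fit
(complete-case per model); the one deliberately different treatment of
missingness is the dedicated module for a covariate absent from an
*entire* validation dataset.

From a fitted model, predicted survival for a covariate pattern is
$S(t \mid x) = S_0(t)^{\exp(PI)}$, with $S_0$ the baseline survivor
function. The forward risk at elapsed seizure-free time $t$ is

$$\mathrm{risk}(t) = 1 - \frac{S(t + w)}{S(t)}, \qquad w = 12
\text{ months},$$

the complement of the conditional probability of remaining seizure
free through the window.

## External validation

Discrimination is measured by Harrell's c-index: the proportion of
comparable patient pairs in which the subject with the earlier
observed event also has the higher risk score (we use the prognostic
index). Under censoring a pair is comparable only when the ordering of
event times is determinable — the member with the shorter follow-up
had the event. Ties are handled by fixed conventions: two events at
the same time are incomparable; an event tied with a censoring time is
comparable with the event treated as earlier; score ties count one
half. These conventions are pinned down by an exhaustive-pair oracle
in the test suite, and they reduce to the familiar values (0.5 chance,
1 perfect) in the limiting cases. The confidence interval uses the
large-sample normal variance of the concordance proportion over pairs;
this understates pair-to-pair correlation and is therefore narrow —
the generalisability verdict does not use it, only the difference in
c between development and validation cohorts, flagged when its
magnitude exceeds 0.05.

Calibration compares mean predicted survival with Kaplan-Meier
observed survival at a horizon (24 months by default) within deciles
of predicted survival; a well-calibrated model puts each decile's
point on the 45-degree line within the observed interval. Deciles are
a package choice — the original plotting routine's internals are not
specified — as is the horizon, which should sit well inside follow-up
for every cohort compared.

Risk groups cut the development cohort's prognostic index at its
16th, 50th and 84th empirical centiles (Cox's grouping, which
minimises the information lost by categorising), giving small low- and
high-risk tails and two larger intermediate groups. Two conventions
are fixed for reproducibility: centiles use the linear-interpolation
(type 7) quantile, and a subject exactly on a cut-point goes to the
lower group. Cut-points are always computed on the development
cohort under the development fit and applied unchanged to validation
cohorts — computing them afresh on a validation cohort would test the
grouping, not transport it. (Whether the original analysis recomputed
the index with validation-fitted coefficients is implicit; we use the
development coefficients, the strict external-transport reading.)

## The missing covariate in FIRST

The seizures-only-while-asleep covariate was never collected in the
FIRST cohort. Five strategies are implemented: (1) variable matching
(refit the development model without the covariate), (2) random
selection with replacement from the development column, (3) single
imputation from the development proportion (Bernoulli draws), (4) hot
deck from development subjects matching exactly on a priority list of
covariates, and (5) repeated random selection averaged per entry.
Averaging a binary covariate is ambiguous, so method (5) resolves at
0.5 by majority with exact ties broken toward the development majority
level, and also returns the continuous per-entry mean; the number of
repeats defaults to M = 10 (no value is prescribed anywhere). Hot-deck
"similarity" is likewise a package decision: exact match on
aetiology, EEG, treatment, then first-degree-relative status, relaxed
from the end of the list until donors exist, with every relaxation
logged. Because FIRST recorded every EEG and CT/MRI (no
"not clinically indicated" option), the development cohort is first
collapsed to the two-level coding when validating against a
FIRST-like cohort; a test never performed carries no normal/abnormal
information, so `not_indicated` maps to missing rather than to either
observed category.

When all four cohorts are pooled, the absent FIRST sleep column is
ordinary missing data within the sleep covariate, and complete-case
fitting then excludes the FIRST rows from the coefficient estimation;
FIRST still contributes to the unadjusted per-arm risk table, which
uses Kaplan-Meier estimates on all pooled subjects.

## Conditional risk and the 20% threshold

For Kaplan-Meier-based curves the variance of
$\log \hat S(t+w)/\hat S(t)$ is the Greenwood sum restricted to the
window, $\sum_{t < t_i \le t+w} d_i / (n_i(n_i - d_i))$ — the
difference of the usual Greenwood accumulator at the window ends —
with the 95% interval formed on the log ratio and complemented. This
windowed sum is our reading of a "revised" Greenwood variance for
conditional survival, which the source literature does not spell out;
a nonparametric bootstrap (resampling subjects within strata,
refitting, recomputing; B = 500 by default, seeded) is provided as
the alternative and is also the interval used for model-based
profiles, where no closed form is attempted.

The baseline survivor is the Breslow-type cumulative hazard at the
reference pattern, exponentiated and joined piecewise-linearly between
event times. Interpolating $S$ itself (rather than $H$) is the literal
reading of a piecewise-linear survivor assumption; the two differ
negligibly at the event-time densities involved. Beyond the last event
time the function is held constant and flagged as extrapolated —
forward-risk windows and threshold searches refuse to enter that
region rather than report an artefactually flat risk.

Threshold crossing times are found by bracketing the continuous risk
function on a fine grid and bisecting to well below 0.05 months, then
reported to one decimal month, the precision at which such crossing
times are conventionally quoted. Risks in the per-arm table are
rounded to whole percent, as printed in the tables this layout
mirrors. The 20% value itself is a configurable parameter, not a
constant: it is a regulatory convention.

Two tie-adjacent numerical choices in the Cox fit: Efron's
approximation for tied event times (the mainstream default of the
survival ecosystem; switchable to Breslow), and Wald 95% intervals on
the hazard-ratio scale. Convergence and separation are checked — a
coefficient beyond ±15 on the log scale aborts with the offending term
named rather than returning a numerically meaningless hazard ratio.

## What the synthetic cohorts emulate — and what they do not

Real patient records for the four studies are available only from the
original study representatives, so the generator stands in for them.
Its defaults encode, per study: the published covariate marginals
(e.g. 16% remote symptomatic in MESS against 57% in NGPSE; 56% of
NGPSE EEGs not clinically indicated; two-level EEG/imaging and 51%
immediate treatment in FIRST), the published multivariable hazard
ratios as generating truth (either the development-model column or the
pooled-model column), an exponential baseline per study, uniform
accrual before an administrative study end (96/48/144/72 months for
MESS/NGPSE/WA/FIRST, echoing the six-year FIRST follow-up and longer
follow-up elsewhere) plus light exponential dropout, and the
missingness structure — the sleep column wholly absent from FIRST,
sporadic missingness where the demographics report it (e.g. 24
first-degree-relative values in WA). Baseline rates (0.030-0.045 per
month) are set so the reference-pattern six-month risk is roughly
15-20%, with WA the highest-risk study; these are generator
parameters, not estimates about any real cohort. FIRST's latent sleep
marginal is unobservable in the real data; the generator draws it at
the MESS rate (18%) so it can drive the hazard before being masked.

Three structural simplifications matter when interpreting green
tests. Covariates are sampled independently, because only marginals
are published — real cohorts correlate EEG findings with aetiology,
so hot-deck imputation faces an easier task here than in practice.
The exponential baseline makes the true forward-risk profile constant
in elapsed time, whereas real first-seizure hazards decline steeply;
threshold-crossing behaviour (risk dipping below 20% at some months)
is therefore exercised with constructed piecewise-linear fixtures
solved analytically, not with generator output. And generated
follow-up is administratively censored, with none of the loss
patterns of long observational studies. Passing tests demonstrate
that the machinery is correct under the stated structure, not that
real cohorts would reproduce any particular table.

Every cohort carries its generating truth (`.true_lp`, `.true_time`)
so parameter-recovery tests are self-contained, and all randomness
flows from one master seed with per-study streams derived
deterministically from it.

## Problem sizes and test design

The test suite checks exact oracles at tiny sizes (exhaustive pair
enumeration up to 8 subjects; hand-computed product-limit and
Greenwood fractions on an 8-subject fixture; a Newton oracle for the
single-covariate Cox score equation) and stochastic properties at
moderate sizes chosen to keep the whole suite around half a minute:
marginal convergence and calibration at n = 10,000, imputation
similarity at n = 5,000, hazard-ratio recovery at n = 20,000 (where
the Monte-Carlo standard error of each refitted hazard ratio is about
0.02-0.03, so recovery within ±0.05 of the generating value is the
natural check). End-to-end pipeline runs use the four published study
sizes (620/274/847/305, 2,046 subjects pooled).

## Known limitations

- No recurrent-event records: only time to second seizure.
- No time-varying covariates, frailty terms, interactions, or
  proportional-hazards diagnostics; no time-dependent AUC, Brier
  score or decision-curve analysis.
- The pairwise-normal c-index interval is anti-conservative; prefer
  the bootstrap flag when the interval itself matters.
- Model-based forward-risk intervals rely on the bootstrap; no
  delta-method alternative is provided.
- The generator's independence and exponential-baseline assumptions,
  as above.
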