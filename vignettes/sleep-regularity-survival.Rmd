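---
title: "Sleep regularity and mortality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep regularity and mortality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

srisurv implements a complete analysis pipeline relating the regularity of a
person's sleep-wake pattern — not its duration or timing, but its
day-to-day repeatability — to time-to-event outcomes. This vignette explains
the statistical machinery, the tunable parameters and their defaults, what
the synthetic cohort generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite and the analysis scripts do not themselves
compute.

## The Sleep Regularity Index

The exposure is built from epoch-level binary sleep-wake series (wake = 0,
sleep = 1, missing = NA) on a fixed grid, 30-second epochs by default. For a
contiguous pair of days, let $p$ be the probability that the person is in
the same state at the same clock time on both days, estimated over all
aligned epoch pairs with both states observed:

$$\mathrm{SRI} = 200\,p - 100.$$

A perfectly periodic sleeper scores 100; a sleeper whose state at each epoch
is an independent coin flip scores 0 in expectation; systematic
anti-alignment is negative. A recording of $k$ valid days yields $k-1$
day-pair values. Three conventions matter:

* **Day boundary.** Days run noon to noon, so a night's main sleep period
  lies inside one day record and is never split. Onset times are reported in
  hours after 18:00 on a linear scale — appropriate for a cohort whose
  onsets cluster at night; a sleeper regularly crossing the 18:00 boundary
  would wrap, which is documented as a hazard of the linear convention.
* **Missingness.** Epoch pairs with a missing member are excluded from both
  numerator and denominator, never imputed. A day pair is *valid* when at
  least `min_pair_fraction` (default 0.8) of a day's epoch pairs are
  observed; participants with fewer than two valid pairs are excluded. (Two
  valid days produce only one pair, so "at least two valid measurements"
  is the operative exclusion rule.)
* **No clipping.** The index is reported unclipped even though cohort values
  land in 0-100 in practice; clipping would bias the mixed-model averaging.

The implementation is verified against a brute-force oracle that enumerates
aligned epoch pairs, exactly, on randomized small series.

## Mixed-model standardization

Day-pair values are averaged with a linear mixed model

$$\mathrm{SRI}_{ij} = \mu + b_i + \beta_{\mathrm{wd}(ij)} +
\gamma\,\mathrm{dst}_{ij} + \varepsilon_{ij}, \qquad b_i \sim N(0,
\sigma^2_u),$$

with a random intercept per participant, fixed effects for the day of week
of the pair's first day (reference Monday), and an indicator for pairs
spanning a daylight-saving transition. Estimation is REML via lme4. The
participant-level standardized SRI is the model prediction for a balanced,
DST-free week: $\hat\mu + \hat b_i + \overline{\hat\beta}$, where
$\overline{\hat\beta}$ averages the weekday effects with equal weight over
the weekdays observed in the data (all seven in a realistic cohort; a
single 7-day recording can only exhibit six pair-leading weekdays, and an
unobserved weekday's effect is inestimable) and the DST effect is set to
zero. $\hat b_i$ is the usual shrunken BLUP — what "averaged with a mixed
model" implies — and a `use_blup = FALSE` switch exposes raw participant
means for sensitivity. Two degenerate regimes are handled exactly rather
than numerically: constant input returns the constant, and a zero
residual-variance boundary triggers an exact projection (within-participant
OLS for the fixed effects, unshrunken participant means), which is the
limit of the BLUP as $\sigma^2_\varepsilon \to 0$.

SD-based comparison metrics — the standard deviations of nightly sleep
duration and of onset time — use the sample SD ($n-1$) over nights with a
detected main sleep period (sleep runs separated by wake gaps under 2 h are
merged; the block with most sleep is the main period).

## Restricted cubic splines

All survival models enter the exposure and every continuous confounder
through restricted cubic splines: piecewise cubics constrained to be linear
beyond the boundary knots, $K$ knots giving $K-1$ columns (the linear term
plus $K-2$ restricted cubic terms). Terms follow Harrell's normalization —
division by the squared span of the outer knots — so coefficients share a
scale. Knots sit at the 10th/50th/90th percentiles for exposures and
confounders and at the 5th/35th/65th/95th percentiles of event times for
the follow-up time axis in discrete-time models; percentiles use the
linear-interpolation (R type 7) definition, stated because conventions
differ across ecosystems. Covariates with a dominant point mass (e.g. pack
years, zero for never-smokers) fall back to a linear term when their knots
collapse.

## Cox models

Cause-specific Cox models (Efron tie handling; deaths from competing causes
censored at the death time) are fit for all-cause, CVD and cancer
mortality, with four covariate sets: the primary confounder list, Model 2
(+ sleep duration, WASO), Model 3 (+ past/prevalent disease), Model 4
(+ BMI, systolic BP, BP medication, physical activity). Hazard-ratio curves
are reported relative to the cohort median exposure, with pointwise
delta-method CIs; the HR at the reference is exactly 1 by construction.
The global test of the exposure is a Wald test of its basis coefficients
(2 df for 3 knots); effect modification adds products between the exposure
basis and the modifier's design columns and Wald-tests the product block.
Wald was chosen because it needs one fit; nested likelihood-ratio
comparisons are available separately and power the SRI-vs-SD-metric
comparison. Missing confounders are multiply imputed upstream and the
per-imputation exposure coefficient vectors pooled by Rubin's rules.

## Discrete-time hazards and standardized risk

Follow-up is expanded into 3-month person-periods and the per-interval
event probability modeled by pooled logistic regression; with quarterly
intervals and low per-interval hazards the logit, cloglog, and Cox
formulations nearly coincide (cloglog available by option), and a package
test confirms the Cox HR and the discrete-time HR agree within 3% under
proportional hazards. The model includes a spline in time, the exposure
spline, covariates, and optionally all time-basis × exposure-basis
products. The Wald test of the product block is the proportionality test;
the fitted products also give time-varying HR curves with delta-method
bands.

Standardized cumulative incidence uses the empirical g-formula: every
analysis-sample row has its exposure set to $s$, per-interval hazards are
predicted, individual risks accumulate as $1-\prod_t(1-h_t)$, and risks are
averaged over rows. With no covariates and a saturated (indicator) time
model this reduces exactly to the actuarial life-table estimator, which the
tests exploit as a closed-form oracle. Confidence intervals come from a
participant-level nonparametric bootstrap (default B = 500; the analysis
scripts use 200) with the spline knots held at their full-sample positions;
bounds are inverse-ECDF percentiles at 2.5/97.5%, so at B = 2 they reduce
to the replicate min/max, a property the tests pin down. Non-converging
replicates are dropped and counted. Following the single-imputation
convention for computationally heavy stages, the discrete-time models
consume the first completed dataset.

## Multiple imputation

Chained-equations predictive mean matching: each incomplete column is
regressed on the other predictors (ordinal factors as integer scores),
coefficients are drawn from their approximate posterior per imputation
(type-1 matching: donors scored with the posterior mean, cases with the
draw), and each missing case copies the observed value of one of
`k_donors = 5` nearest-predicted-mean donors. Imputed values therefore
always lie in the observed support — a categorical column never receives an
unseen level. Defaults: m = 10 imputations, 5 chained iterations, visit
order by increasing missingness. Pooling uses Rubin's rules with
Barnard-Rubin small-sample degrees of freedom (classical
$(m-1)/\lambda^2$ when the complete-data df is infinite); m = 1 passes
through with a flag.

## The synthetic cohort generator

Because the motivating cohort is access-controlled, every stage runs
against a generator with known ground truth:

* **Sleep.** Each night has one main sleep period; onset and duration are
  Gaussian around participant-level means (onset 23:00, duration 8 h by
  default), truncated to [0.5, 16] h. Night-to-night SDs are the
  ground-truth (ir)regularity and can vary per participant (the analysis
  scripts draw onset SDs uniformly on 0.1-2.5 h). Awakenings are Poisson
  bouts (2/night, mean 15 min) of wake inside the sleep period; nonwear is
  a per-day 5% chance of a 4 h missing run; DST is a relabeling of clock
  time from a given day onward, exactly as a device recording local time
  would show it. Any controllable-variance family would serve; Gaussian
  noise was chosen for interpretable SDs. The generator does not emulate
  naps, raw accelerations, or circadian physiology — so passing tests
  demonstrate correctness of the *estimators*, not robustness to every
  feature of real recordings.
* **Survival.** Event times are exponential with rate
  $\lambda_0 e^{f(\mathrm{SRI})}$, administrative censoring (7.1 y), and a
  cause mix of 20% CVD / 57% cancer / 23% other, matching the cohort
  structure the pipeline emulates. Ground-truth shapes include null,
  log-linear, threshold, and a convex "ushape" centered near the top of
  the generator's SRI range (center 80, HR 1.5 at 30 units below), so risk
  is highest for the most irregular sleepers and flattens above the median
  — the qualitative pattern the pipeline is designed to detect. The
  quadratic's parameters were set once against the generator's SRI scale
  (median ≈ 70, 5th percentile ≈ 49 under script defaults).
* **Missingness.** MCAR per column at a configurable rate (2% default,
  matching "infrequent" confounder missingness); outcome columns are
  protected.

## Problem sizes and numerical tolerances in the test suite

The suite verifies parameter recovery at sizes chosen to make the
asymptotic statements testable on one CPU in minutes: log-linear Cox
recovery uses 200 replicates of n = 20,000 (bias < 2 Monte-Carlo SEs);
U-shape recovery uses one n = 20,000 cohort with a 5-knot exposure spline
(a symmetric U needs more curvature than 3 knots provide); the
proportionality test's size uses 500 replicates at n = 2,000 (99% binomial
bounds around 0.05 — at a few hundred events the 6-df Wald test is still
slightly conservative, so the size check is run where its asymptotics
apply); the early-excess scenario (true HR 2 before 2.5 y, 1.5 after) uses
n = 30,000 with a 12% band on window-averaged time-varying HRs, accepting
the smoothing a spline applies to a step; bootstrap coverage uses 200
replicates × B = 200 at n = 250 with mean coverage required in
[0.90, 0.99]. Exact identities (SRI calibration points, spline tail
linearity at 1e-10, the life-table oracle at 1e-7, Rubin arithmetic) are
asserted at machine-level tolerances.

## Known limitations

Linear onset scale (wraparound for day sleepers); no nap handling; the
main-sleep-period rule assumes gaps under 2 h within a night's sleep; MCAR
(not MAR/MNAR) missingness in the generator; percentile (not BCa)
bootstrap; single imputation for the discrete-time stage by design; no
frailty, left truncation, or age-as-timescale variants; PMM treats
unordered categories via integer scores, which is standard but loses
category structure when a column has many unordered levels.
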