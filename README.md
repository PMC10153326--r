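# srisurv — sleep regularity and survival analysis

Irregular sleep — going to sleep and waking at different times from day to
day — is an emerging risk factor for mortality, distinct from short or
disrupted sleep. `srisurv` is an R package plus a reproducible analysis
workflow for studying that question end to end: it scores epoch-level
sleep-wake series into the **Sleep Regularity Index (SRI)**, standardizes it
with a mixed model, and relates it to time-to-event outcomes with
restricted-cubic-spline Cox models, discrete-time hazards models with
time-varying hazard ratios, and bootstrapped standardized cumulative
incidence. Because cohort accelerometry data of this kind are
access-controlled, the package ships a synthetic cohort generator with known
ground-truth regularity, so every stage is testable by parameter recovery.

It is intended for epidemiologists and biostatisticians working with
wearable-derived sleep data, and for anyone who wants a tested reference
implementation of this analysis pattern.

## The statistics

**SRI.** For a contiguous day pair, with `p` the fraction of aligned,
non-missing epoch pairs in the same sleep/wake state at the same clock time
24 h apart,

    SRI = 200 p − 100

so identical days score 100 and independent random days score 0 in
expectation. A k-day recording gives k−1 day-pair values, which are averaged
by a linear mixed model with a participant random intercept and fixed
effects for day of week and daylight-saving transitions; the standardized
SRI is the model-predicted mean over a balanced, DST-free week
(`μ̂ + b̂ᵢ + mean(weekday effects)`).

**Survival models.** The SRI and all continuous confounders enter Cox
models as restricted cubic splines (knots at the 10th/50th/90th
percentiles, Harrell normalization); hazard ratios are reported relative to
the median SRI, with a 2-df Wald test of the spline term. Discrete-time
(pooled logistic) models on 3-month person-periods with a time × SRI
interaction test proportionality and trace time-varying HRs; g-computation
over the analysis sample yields standardized cumulative incidence at fixed
SRI values, with participant-bootstrap CIs. Missing confounders are
imputed by chained-equations predictive mean matching and pooled by
Rubin's rules.

See `vignettes/sleep-regularity-survival.Rmd` for the full methods account.

## Worked example

The `analysis/` directory is a numbered workflow over the package —
simulate, score, standardize, model — driven by `analysis/config.yaml`
(1,500 participants, 7 nights of 30-s epochs, a convex ground-truth
log-hazard in true regularity). Run it from the repository root:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_score_regularity.R
Rscript analysis/03_standardize_sri.R
Rscript analysis/04_survival_models.R
Rscript analysis/05_discrete_time.R
```

Output from a run at the default configuration:

```
8968 day-pair SRI values from 1500 participants (99.6% valid pairs).
Mixed model: grand mean 67.7, var(participant) 143.9, var(residual) 333.6.
Standardized SRI: 5th 48.9, median 70.1, 95th 81.2.
330 deaths (22.0%) over 7.1-year administrative follow-up.
All-cause HR vs median SRI: 1.67 at 5th pct, 0.94 at 95th pct (pooled over m = 5).
Global spline test: chi2 = 16.7 on 2 df, p = 0.00024.
Proportionality (time x SRI Wald): chi2 = 2.9 on 6 df, p = 0.818.
Standardized 7.2-year risk: 31.1% (SRI 49), 20.2% (SRI 70), 18.9% (SRI 81).
```

Reading this: the most irregular sleepers (5th SRI percentile) have a 67%
higher all-cause mortality hazard than the median sleeper, while very
regular sleepers sit slightly below it — the convex exposure-response the
generator encodes, recovered by the spline Cox model (global p < 0.001).
The simulation is proportional-hazards by construction, and the time × SRI
interaction test correctly finds no evidence against proportionality
(p = 0.82). The standardized 7-year risk curves are ordered accordingly:
31% for irregular vs ~19-20% for median and regular sleepers. Tables
(HR curves, time-varying HRs, risk curves with bootstrap CIs) land in
`results/`.

Equivalently, `run_pipeline(default_run_config())` executes the same stages
in one call and returns a run report.

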