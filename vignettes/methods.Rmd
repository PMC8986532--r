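---
title: "Models and methods: epigenetic ageing across hibernation cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: epigenetic ageing across hibernation cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibernage)
```

`hibernage` asks whether epigenetic ageing stalls during hibernation in a
longitudinally sampled wild mammal. This vignette is the package's own
account of the models it fits, the choices behind their defaults, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The time axis

All circannual structure lives on a study day-of-year with day 1 = 1 May
and day 365 = 30 April, so a single hibernation (days 139–352, i.e. 16
September – 17 April) falls inside one cycle. The active season spans the
wrap: days 353–365 followed by days 1–138 of the next study year, 151 days
in total. Field sampling is narrower still, days 362–365 and 1–112 (27
April – 20 August). Leap days are rejected rather than remapped: the
cyclic spline period is fixed at 365 and a one-day shift is far below any
effect of interest. `calendar_to_study_doy()` is bijective on the 365
non-leap dates and ingest converts 1-January-origin Julian days with an
explicit `doy_origin` switch — the convention is never assumed silently.

Because an active season straddles the study-year boundary, a sample's
*season index* is its study year plus one when its day-of-year is ≥ 353;
"consecutive years" for the rate contrast means consecutive season
indices. This makes seasons unambiguous: every hibernation separates
exactly two adjacent indices.

## Epigenetic pacemaker

The pacemaker models methylation at site *i* in sample *j* as
`β_ij = r_i s_j + o_i + ε_ij` with a shared latent state `s_j`. Fitting
alternates two exact conditional minimizers of the residual sum of
squares: per-site ordinary least squares of `β` on the current states, and
the closed-form state update
`s_j = Σ_i r_i (β_ij − o_i) / Σ_i r_i²`. Each half-step can only lower the
RSS, so the trajectory is monotone (asserted on the stored trace) and the
iteration stops when the relative RSS change drops below `tol = 1e-6`
(cap: 1000 iterations — the linear-algebra structure typically converges
in well under ten).

States are identified only up to an affine transformation: rescaling all
states and compensating the site parameters leaves the fit unchanged.
Initializing states at chronological ages anchors this gauge in
pseudo-year units, which is why fitted states sit on the age scale and why
all recovery tests compare states only after least-squares affine
alignment. Site selection keeps sites with |Pearson r| > 0.7 between
methylation and age (zero-variance sites are dropped with a warning);
cross-validation re-selects sites inside each training fold by default so
held-out states carry no selection leakage — the alternative (select once,
globally) is a switch, since either reading of the original protocol is
possible.

## Epigenetic clock

The clock is an elastic-net regression (glmnet) of age on methylation with
mixing weight α = 0.5 and the penalty chosen at the minimum mean
cross-validated squared error. Predictors are standardized before
penalization (the common default; recorded in the model artifact, and
switchable, since the original fit's choice is not documented).
Out-of-sample ages come from `grouped_holdout_predictions()`: contiguous
blocks of ~14 samples after a seeded shuffle, one model per block trained
on the remainder — 149 samples at group size 14 gives 11 models. Accuracy
is summarized by Pearson r, median absolute error (years) and median
relative absolute error; the relative error divides by observed age and
therefore skips exact-zero ages, which cannot occur in this design (the
youngest sampling age is 0.01 years) but must be guarded generically.

## GAMM engine

Seasonal inference uses Gaussian additive mixed models built on mgcv:
a cubic regression spline for age (`bs = "cr"`, k = 10), a cyclic cubic
spline for day of year (`bs = "cc"`, k = 10, knots spanning [1, 366] so
that value, first and second derivatives match across the 365 ↔ 1
boundary), an optional tensor-product interaction (`ti`, interaction-only,
one penalty per margin), and an animal random intercept as a
ridge-penalized factor smooth. k = 10 is the conventional default for a
single smooth covariate; it bounds each term's effective degrees of
freedom well above anything the data support. In the tensor term the
cyclic margin keeps its full basis (so its knots can be shared with the
marginal smooth) while the other margin is trimmed to 5, keeping the
interaction's coefficient count modest relative to n = 149.

Eight fixed-effect structures are compared: age and day-of-year linear;
their linear interaction; each promoted to a spline; day-of-year promoted
to a cyclic spline; and the tensor interaction added to the two marginal
smooths. Candidates differing in fixed effects are compared by ML-based
AIC — REML likelihoods are not comparable across fixed-effect structures —
with a winner declared only at ΔAIC > 2. Final single-model reporting and
the per-site scans use REML, the more stable smoothness-selection
criterion. Smooth-term tests are mgcv's Wald-type tests on the penalized
coefficient covariance, reported in the conventional
{edf, reference df, F, p} shape; exact numerical equality of edf/F with
other software's defaults is not expected, and only the intercept, signs
and significance pattern are treated as reproducible quantities.

## Seasonal inference

Two simulated traits drive the power and type-I analysis on a fixed
sampling design. The non-seasonal trait accrues 0.004 state-units per day
of age; the seasonal trait accrues only on active days and stalls during
winter. The published account of the seasonal rate is internally
inconsistent — the stated value (0.0164/day) and its own defining formula
(0.004/365 × 150 = 0.00164/day) differ tenfold — so the package defaults
to the rate that makes the two traits' annual accrual equal
(0.004 × 365 / 151 ≈ 0.00967/day, the stated design goal) and exposes the
other readings via `active_daily_rate`. The acceptance script runs all
three. Animal intercepts (variance 0.329) and residuals (variance 0.294)
use the variance components reported for the fitted state model. Per
replicate the carried-forward GAMM (spline age + cyclic day-of-year +
animal intercept) is refitted and the seasonal term's p recorded;
the model selection itself is not rerun per replicate, matching a design
in which the best model is fixed first. Non-convergent replicates are
excluded from the denominator with a logged count.

The permutation null shuffles day-of-year labels against the observed
states. Both null routes report the rejection proportion at α = 0.05 and
the 0.05 quantile of the null p distribution — the adjusted critical value
that restores a 5% error rate when the nominal test is anti-conservative.
Calibration is verified split-half: a threshold estimated on half the null
replicates yields close-to-nominal rejection on the held-out half.

The rate contrast subsamples animals with ≥ 2 samples in one season and
≥ 1 in the adjacent season. The active rate divides the state difference
between the latest and earliest sample of the ≥ 2-sample season by the
days between them; the hibernation rate divides the state change from the
last sample before the intervening winter to the first sample after it by
that day span. Group differences use the tie-corrected Kruskal–Wallis H
with a χ² reference; completely tied inputs define H = 0 (the
tie-correction denominator would vanish, and "no separation" is exactly
what the statistic should say).

## What the synthetic generator emulates — and what it does not

`generate_design()` reproduces the design-level facts: 73 females, 149
samples, 1–8 per animal, ages 0.01–12.04 years with both endpoints
realized, sampling confined to the field window, within-season recaptures
10–60 days apart (biweekly trap sessions, recaptures one to a few sessions
later), and exactly 11 animals sampled in consecutive seasons. Ages at
last capture are stratified uniformly because the original samples were
deliberately selected to span ages; a right-skewed wild-population age
structure is available through `age_scale`. Birth (natal emergence) days
fall in early summer, days 30–90.

`generate_study_table()` adds a latent state with the features the
analysis is designed to detect: accrual only on active days; a concave age
profile (`adult_rate` 0.55, `boost` 4.5, `tau` 1 active-year) in which
roughly half the lifetime state gain is reached by sexual maturity at two
years; and an affine alignment onto the age axis, because age-initialized
pacemaker states live in that gauge — the GAMM intercept is then an
emergent consequence of the mean sampled age, not a constant anyone set.
The within-animal deviation splits the reported residual variance into a
slowly varying trajectory process (exponential autocorrelation, 730-day
time scale) plus a small measurement error (sd 0.1): latent states
estimated from hundreds of CpGs carry little sampling noise, and a fast
iid residual of the full reported magnitude would reduce short-interval
ageing rates to pure noise, contradicting the very contrast the table
exists to emulate. A consequence worth knowing: the fitted GAMM residual
variance on synthetic tables is smaller than the reported 0.294, because
the intercept and trajectory absorb most deviation.

The generator does **not** emulate probe-level array artifacts, batch
effects, SNP-confounded probes, or the 31,388-site scale of the real
array (defaults: 400 sites, 309 of them age-informative, Gaussian noise
sd 0.03 clipped to [0,1]). Passing tests therefore demonstrate that the
estimators recover the structure they assume, at realistic sizes — not
that the assumptions hold in any particular array dataset. One structural
limit is intrinsic: with a single latent state driving every informative
site, clock predictions are affine in that state, so the clock retains the
seasonal signal on synthetic methylation matrices; the empirical finding
that penalized age regression erases seasonality can only be emulated at
the table level (the synthetic clock-age column tracks chronological age),
not reproduced from synthetic betas.

Power under this emulation is high (near 1 at both published seasonal-rate
readings, near the nominal level at the literal formula value): the
synthetic design's day-of-year leverage makes the seasonal term easier to
detect than in the original data, whose per-animal capture patterns are
not public. The intermediate published power value is therefore not a
quantity this generator reproduces, and the acceptance suite says so
honestly rather than bending rates toward it.

## Numerical choices and degenerate inputs

Pacemaker: `tol = 1e-6` relative RSS, `max_iter = 1000`; all-zero site
rates raise a degenerate-model error; zero-variance training sites are
dropped with a warning. Clock: constant response is an error; folds are
seeded and recorded. GAMM: smooths are centered so the intercept is
identifiable; random-intercept variance may hit the zero boundary without
error; non-convergence flags the fit rather than failing silently.
Beta I/O validates every value into [0,1] and names the offending cell.
Kruskal–Wallis at complete ties returns H = 0. All stochastic stages take
explicit seeds and every artifact records the seed that produced it.

## Problem sizes

The test suite runs the full design (149 samples) for the table-level
checks, 300-site matrices for recovery properties, and reduced replicate
counts (40–500) for simulation operating characteristics, with tolerance
bands widened by the corresponding binomial noise. The acceptance script
defaults to 500 replicates per simulation; its JSON records the size `n`
behind every number.
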