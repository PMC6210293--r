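---
title: "Methods: wrist cut-point calibration from quantile-matched synthetic counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist cut-point calibration from quantile-matched synthetic counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcal)
```

## Why a synthetic cohort

The calibration protocol this package models — children aged 5–11
performing eight seated sedentary activities and slow walking with an
accelerometer on each wrist, posture verified by direct observation — was
never deposited as raw data. What survives are per-activity summaries:
each wrist's median and interquartile range of axis-1 counts per 5-s
epoch, the estimated wrist contrasts at the three quartiles, and the
derived cut-points. `wristcal` therefore treats the published marginal
quantiles as calibration targets for a generative model, and re-runs the
entire downstream analysis on cohorts drawn from that model. Everything a
user can compute — contrasts, thresholds, AUCs, sedentary minutes — is
produced by the same code paths a real epoch export would flow through.

## The count model

Counts per 5-s epoch for one activity on one wrist are modelled as
zero-inflated lognormal (ZILN): with probability $\pi$ the epoch records
exactly zero counts; otherwise the count is lognormal with log-location
$\mu$ and log-scale $\sigma$. The quantile function is

$$Q(\tau) = \begin{cases} 0 & \tau \le \pi \\
\exp\!\big(\mu + \sigma\,\Phi^{-1}\!\big(\tfrac{\tau-\pi}{1-\pi}\big)\big) & \tau > \pi.
\end{cases}$$

This family was chosen because the published rows are right-skewed,
strictly non-negative, and frequently zero-heavy (several activities have
a zero 25th or even 50th percentile). Any three-parameter family that can
interpolate a quantile triple would serve; ZILN is the documented default
and the only one implemented.

### Fitting conventions

`fit_ziln(q25, q50, q75)` matches the three parameters to the triple:

* **All three positive.** $(\mu, \sigma)$ have a closed form through
  $q_{50}$ and $q_{75}$ at any candidate $\pi$, so $\pi \in [0, 0.25)$ is
  found by 1-D root finding (tolerance $10^{-9}$) such that $Q(0.25)$
  matches $q_{25}$. Triples whose left tail is *lighter* than any
  lognormal through the upper two quantiles are rejected — zero-inflation
  can only thicken the left tail.
* **$q_{25} = 0 < q_{50}$:** $\pi = 0.25$ with the closed form above.
* **$q_{50} = 0 < q_{75}$:** $\pi = 0.5$; the 75th percentile then pins
  only $\mu$ ($Q(0.75) = e^{\mu}$ at $\pi = 0.5$), so $\sigma$ is
  borrowed from the opposite wrist's fit for the same activity, or 1 if
  none exists. These rows are under-identified by the published summary
  and the convention is deliberately explicit.
* **All zero:** $\pi = 0.75$, $\mu = \log 1$, $\sigma = 0.5$ for quantile
  evaluation. At *generation* time an all-zero target triple is treated as
  "no recorded movement" and emits structural zeros: the published row for
  the stillest activity (TV, non-dominant) gives no information about an
  upper tail, and fabricating one would leak spurious counts into every
  downstream contrast.

Fits reproduce every positive target to relative accuracy $10^{-6}$; the
degenerate case $q_{50} = q_{75} > 0$ is admitted with $\sigma = 0$ (a
point-mass positive part).

## The cohort generator

`generate_dataset()` draws, for each child × activity, paired wrist series
of `epochs_per_activity` epochs (default 60, i.e. the protocol's 5-min
bouts at 5 s):

* **Cross-wrist coupling.** A Gaussian copula links the wrists epoch by
  epoch: latent $z_d$, $z_n$ with correlation $\rho$ are pushed through
  each wrist's fitted quantile function. Defaults: $\rho = 0.95$ for
  walking (gait moves both wrists nearly identically) and $\rho = 0.5$
  for seated tasks. The copula touches the joint law only; each wrist's
  marginal is exactly the fitted ZILN.
* **Child clustering.** One multiplicative lognormal effect per child
  (log-SD `child_effect_sd`, default 0.3) multiplies all of that child's
  positive counts on both wrists and every activity. The within-child
  log-scale is deflated to $\sqrt{\sigma^2 - \text{sd}_c^2}$ so that the
  population marginal, with the child effect integrated out, still matches
  the targets; medians are preserved exactly because the effect's median
  is 1. The published tables report no between-child dispersion, so 0.3 is
  a package choice: large enough that cluster-aware and naive inference
  differ materially, small enough that per-activity distributions remain
  within the realm the published IQRs suggest. It is a config knob, not a
  fitted quantity.
* **Axes 2 and 3.** No published axis-2/3 descriptives exist; axes 2 and
  3 are the axis-1 draw scaled by 0.7 and 0.6 with independent lognormal
  noise (0.2 log-units) — synthetic conventions, flagged as such.
  Vector magnitude is computed from the epoch-level axis counts, which
  diverges from device firmware that accumulates VM per raw sample.
* **Contamination.** With probability `p_stand` (default 0.05) a seated
  child×activity session is contaminated: a contiguous run covering
  10–50% of the bout (length uniform on that range, position uniform) is
  replaced by walking-distributed epochs on both wrists, and the
  observation log flags the session `seated_verified = FALSE`. This is
  what the inclusion filter is for; the run-length convention is the
  package's own, since only the exclusion rule, not the contamination
  process, is described.
* **Integerization.** Positive draws are rounded to the nearest integer
  *after* the child effect, since device exports carry integer counts.

What the generator does **not** emulate: raw sub-second accelerations,
diurnal or fatigue trends within a bout, age/sex effects on counts, count
autocorrelation within a series (epochs are exchangeable given the child),
and monitor-specific filtering artifacts. Passing tests therefore
demonstrate that the statistical machinery is correct and well-calibrated
to the published marginal structure — not that it has been validated
against raw free-living data.

## Wrist contrasts

The published contrast at quantile level $\tau$ is the coefficient of the
wrist indicator in a quantile regression. With a single binary covariate
the design is saturated, so that coefficient *is* the difference of the
two groups' $\tau$-quantiles; `quantile_diff()` computes it that way
under one fixed convention — linear interpolation between order statistics
at position $(n-1)\tau$ ("type 7"). The test suite cross-checks the
equivalence against an independent check-loss quantile-regression fit in
the configurations where that fit's solution is unique.

Confidence intervals come from a **clustered bootstrap**: children (never
epochs) are resampled with replacement, each sampled child contributing
its complete epoch blocks on both wrists; the 95% interval is the
percentile interval over B = 100 replicate contrasts. Percentile rather
than BCa intervals because B = 100 — the protocol's own replicate count —
is too small to estimate acceleration stably; B is configurable. A
contrast is reported **non-converged** (mirroring the dashes in the
published table) when the replicate distribution is degenerate or when
both wrists' point quantiles sit in the atom at zero; whether the original
dashes reflect solver failure or degenerate quantiles is unknowable from
the text, and both conditions are flagged identically. "Significant"
means the 95% interval excludes zero — the reproducible reading of the
published bold-at-$p \le 0.05$ marks, which never name a test.

## Cut-point derivation

`calibrate()` reads the "10-fold ROC analysis" as child-level k-fold
cross-validation nested inside a one-off calibration/validation split,
because the protocol reports both a 10-fold procedure and a separate
100/67-children split:

1. Children are split once (seeded) into calibration and validation sets
   (fraction 100/167 by default). Both the split and the folds operate on
   children, never epochs, to respect clustering.
2. Calibration children are partitioned into $k = 10$ folds. For fold $i$
   the Youden threshold is derived on the other nine folds and its
   sensitivity, specificity and AUC are evaluated on fold $i$
   (out-of-fold by default; in-fold evaluation is available since the
   original description is ambiguous).
3. Thresholds and metrics are averaged over folds. Fold-mean AUC gets a
   normal-approximation CI (mean ± 1.96·SD/√k).
4. The averaged threshold is applied to the validation children; their
   AUC gets a percentile CI from a child-level bootstrap (B = 200),
   chosen for implementation simplicity over analytic variance formulas.

The alternative reading — ten independent repetitions rather than ten
folds — is implemented as `mode = "repeats"` (child-level bootstrap
resamples of the calibration set, evaluated in-sample).

Only walking and the *single highest-count seated activity* (selected by
median, ties by 75th percentile then lexicographically) enter the ROC:
a threshold separating the busiest seated task from walking classifies
every quieter seated task a fortiori, and pooling all seated activities
would inflate apparent accuracy. A pooled mode exists but is off by
default.

**Youden details.** The classification rule is `count ≥ threshold ⇒
light`; sensitivity is anchored on the light class (the original never
says which class anchors it; this choice makes the two metrics nearly
symmetric, as published). Candidate thresholds are all distinct observed
counts plus one beyond the maximum; ties in sensitivity + specificity go
to the smallest threshold, with a $10^{-9}$ fuzz so floating-point noise
in the percentage sums cannot override the tie-break. AUC is the midrank
Mann–Whitney statistic, identical to the trapezoidal area under the
empirical ROC curve; the tests verify it against an all-pairs brute-force
oracle and an external ROC implementation.

## Classification and summaries

`classify_epochs()` applies `count < cutpoint ⇒ sedentary` — the boundary
convention inherited from the Youden rule (the original states neither ≥
nor >). `summarize_intensity()` converts label tallies to minutes with the
total defined as the sum of the two classes, so conservation holds exactly
in floating point. No bout-length or breaks-in-sedentary logic is applied,
and wear-time handling is out of scope: the summary assumes a fully
classified wear period.

## Numerical and reproducibility choices

* All stage seeds are explicit config fields; `set_pipeline_seed()`
  derives generator/bootstrap/calibration seeds from one master seed.
  Identical configs give byte-identical pipeline outputs (the manifest
  carries MD5 checksums and no timestamps).
* Root finding uses bisection-safe `uniroot` with tolerance $10^{-12}$ on
  $\pi$; fitted quantiles are verified to $10^{-6}$ relative error at fit
  time.
* Degenerate inputs are first-class: empty classes, single-activity
  tables, all-zero activities, folds missing a class (skipped with a
  warning; an all-skip is an error), and fully contaminated cohorts
  (the pipeline aborts at calibration, naming the stage).

## Problem sizes used by the test suite

The packaged checks run a 150-child cohort with 60 epochs per activity
for parameter-recovery and ordering checks, $10^5$ epochs for marginal
calibration of the generator, 200 random instances per brute-force oracle
equivalence, and 200 simulation replicates (n = 150 children, B = 100)
for bootstrap-coverage assessment — sizes at which the published-scale
quantities stabilize while the whole suite stays interactive.

## Known limitations

* The ZILN family is an interpolating stand-in: any family matching three
  quantiles is observationally equivalent given the published summaries,
  and tail behaviour beyond the 75th percentile is extrapolation.
* The under-identified zero-median rows inherit $\sigma$ from the
  opposite wrist; contrasts at the 75th percentile for those activities
  are sensitive to that convention.
* Cut-points derived on synthetic cohorts recover the *structure* of the
  published results (ordering of wrists' thresholds and AUCs, the
  threshold bracketed between the reference-activity and walking medians)
  but not their exact values, which depend on unavailable raw data.
* AUC values on the synthetic cohort run higher than published
  (≈ 0.75–0.77 vs 0.72) because exchangeable ZILN epochs understate
  real-world within-class heterogeneity.
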