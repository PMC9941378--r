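---
title: "Hypotension exposure and hinge threshold regression: methods"
author: "bphinge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypotension exposure and hinge threshold regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bphinge)
```

## The scientific question

In septic ICU patients, how much hypotension — and in which blood-pressure
component — is associated with mortality and organ dysfunction?  Clinicians
titrate vasopressors against mean arterial pressure (MAP), but systolic
(SBP), diastolic (DBP), and pulse pressure (PP = SBP − DBP) plausibly affect
organ perfusion differently.  `bphinge` implements the full analytical
chain for this question: raw bedside blood-pressure readings are cleaned and
resampled to a one-minute grid, reduced to per-patient exposure statistics,
and related to outcomes with spline and change-point (hinge) logistic
regression.  Because real septic-ICU vital-sign databases are access
restricted, the package ships a synthetic cohort generator with known
ground truth; every stage is validated against that truth.

## Exposure definitions

Two exposure statistics are computed per component over the window from ICU
admission to outcome onset or discharge, whichever is earlier:

* **Lowest sustained value.** The smallest pressure $v$ such that the
  patient spent at least $d$ cumulative — not necessarily consecutive —
  minutes at or below $v$; equivalently the $d$-th smallest minute value.
  The default $d = 120$ minutes reflects the duration at which a
  clinically meaningful mortality increase has been reported.
  `lowest_sustained()` computes it by partial sorting;
  `lowest_sustained_bruteforce()` is an independent integer-threshold scan
  kept solely to validate it.
* **Time-weighted average (TWA) below a threshold.**
  $\mathrm{TWA} = \sum_t \max(0, \tau - x_t) / \mathrm{LOS}$, a combined
  depth-and-duration dose in mmHg.  The default thresholds $\tau$ are the
  change-points estimated for ICU mortality (MAP 69, SBP 100, DBP 60,
  PP 57 mmHg).  The denominator is ambiguous in principle — total ICU
  length of stay or the outcome-truncated exposure window; both are
  implemented (`twa_denominator`), and total LOS is the default because
  the statistic is explicitly a length-of-stay standardization.

## Preprocessing rules

Raw readings pass through, in order:

1. **Plausibility filters** (inclusive boundaries): SBP ≥ 300 or ≤ 20;
   SBP ≤ DBP + 5; DBP ≥ 225 or ≤ 5; MAP ≥ 250 or ≤ 10 mmHg.  A match
   removes the whole reading, and the removal log records every matched
   reason.
2. **Derivation at reading level**: MAP = (2·DBP + SBP)/3 only where no
   measured MAP exists; PP = SBP − DBP wherever both are present.  PP is
   derived *before* interpolation and interpolated as its own series:
   interpolating SBP and DBP separately and subtracting can differ when
   their reading times differ.  One consequence of integer rounding is
   that the minute-level identity PP = SBP − DBP can be off by 1 mmHg; the
   identity holds exactly before rounding.
3. **Source merging**: invasive values win at any minute that has one;
   non-invasive (cuff) values fill the rest.  Two same-source readings in
   one minute resolve to the later one, with the collision counted.
4. **Interpolation**: linear between consecutive measured minutes, rounded
   half-up to integers (the convention for "rounded to the nearest
   integer" here; R's default round-half-even would differ at .5 ties).
   No extrapolation beyond the first/last reading of a component, and a
   component with a single reading is marked insufficient.
5. **Eligibility**: a patient is excluded when any gap in the pooled
   reading stream strictly exceeds 120 minutes.  Gaps from window start to
   the first reading and from the last reading to window end count too: an
   unmonitored first three hours is the same evidence problem as an
   internal gap.  The rule is evaluated on the pooled stream, not per
   component.

## The hinge (threshold) model

The core estimator assumes outcome log-odds are flat above an unknown
change-point $e$ and linear below it:

$$\operatorname{logit} P(y=1 \mid x, z) \;=\; \alpha + \beta_d \max(0,\, e - x) + \gamma^\top z,$$

with $\beta_d \ge 0$ the log-odds increase per mmHg of pressure *deficit*.
The reported pre-threshold **slope** is $-\beta_d$, the slope of the
log-odds in the pressure itself, so more negative means a stronger
association; it is also reported per standard deviation of the exposure so
components on different mmHg scales can be compared.  $e$ is estimated by
profile likelihood: every integer candidate between the 5th and 95th
exposure percentiles is tried, the remaining coefficients refit at each
(via iteratively reweighted least squares, `glm.fit`), and the candidate
maximizing the profile log-likelihood is reported, with ties broken to the
smallest candidate for reproducibility.  Two diagnostic flags are raised:
`boundary` when the maximum sits at a grid edge, and `flat_profile` when
the hinge term fails a $\chi^2_1$ screening comparison against the
no-deficit null.  Confidence intervals for $e$ and the slope come from a
percentile bootstrap resampling patients (default 200 replicates), since
standard Wald theory does not apply to the change-point.  The reported
plateau log-odds is evaluated at the covariate means, matching how
predicted curves condition on covariates.

## Spline risk curves and the remaining estimators

* `fit_spline_logistic()` fits the additive penalized logistic model with
  low-rank thin-plate regression splines and smoothness chosen by
  generalized cross-validation, delegating to `mgcv::gam(method =
  "GCV.Cp")` — the canonical implementation of exactly this estimator.
  The basis dimension is `k = 10` per smooth.  `predict_probability_curve()`
  conditions other covariates at means (continuous) or reference levels
  (categorical), uses delta-method intervals on the link scale, and
  refuses to extrapolate.  GCV occasionally leaves residual wiggle in a
  truly null smooth on a single realization; the package's validation
  asserts shrinkage (effective degrees of freedom near 1) on the median
  across replicates.
* `binned_moving_average()` gives the model-free univariable curve: 100
  equal-count bins by sorted exposure (remainder spread over the first
  bins), per-bin outcome proportion, and a centred 5-bin simple moving
  average whose windows shrink at the edges.
* `categorical_or()` reproduces the threshold-table design: overlapping
  "< cutoff" groups each contrasted against one fixed normotensive
  reference (MAP ≥ 75, SBP ≥ 110, DBP ≥ 60, 40 ≤ PP < 50 mmHg) in an
  adjusted logistic model, with crude n/event/% columns alongside.
* `subgroup_analysis()` refits the exposure model per stratum with the
  grouping variable removed from the covariates.
* `gvif()` computes generalized variance inflation factors by the
  determinant-ratio formulation on the design-column correlation matrix,
  reporting $\mathrm{GVIF}^{1/(2\,\mathrm{df})}$ for multi-column terms.

## Cohort construction

`compute_sofa()` implements the standard six-organ 0–4 scoring; a missing
organ input scores 0 — a conservative, openly stated choice that keeps the
sepsis gate deterministic.  Sepsis requires infection evidence (admission
diagnosis or antibiotics for more than 48 h) plus day-1 SOFA ≥ 2; septic
shock is operationalized as lactate > 2 mmol/L with vasopressor use, and a
missing lactate can never satisfy it.  ICU mortality is assessed only from
24 h after admission; myocardial injury onsets at the first troponin
strictly above 0.03 ng/mL.  The exclusion cascade attributes each patient
to the *first* criterion failed, so attrition counts always sum back to the
input size.  Norepinephrine-equivalent rates divide factor-weighted
cumulative doses (mcg) by weight (kg) and ICU stay (min); the conversion
factors are configuration with literature-convention defaults
(norepinephrine 1, epinephrine 1, dopamine 0.01, phenylephrine 0.1,
vasopressin 2.5 per unit, dobutamine 0), because no single published table
is authoritative.

## The synthetic cohort generator

The generator emulates the structure of a large multi-centre septic ICU
database, not its physiology:

* **Latent trajectories.** Per patient, MAP and PP follow mean-reverting
  AR(1) fluctuations (stationary SD 2.5 mmHg, lag-1 correlation 0.95)
  around baselines (MAP 78 ± 7, PP 40 ± 9 mmHg).  One sustained primary
  hypotensive episode (≥ ~130 min, exponential extension) pulls MAP to a
  patient-specific target drawn N(62, 10) — this makes the *true* lowest
  MAP sustained 120 min directly controllable — and shorter, shallower
  dips are superimposed (0.05/h, mean depth 8 mmHg, 20–80 min).  DBP is
  derived as MAP − PP/3, SBP as DBP + PP, so MAP = (2·DBP + SBP)/3 and
  SBP > DBP + 5 hold exactly in the truth.  The realized true exposure
  distribution is slightly below and tighter than its target
  (≈ 60 ± 8.5 mmHg) because AR noise shifts the 120th order statistic and
  high targets truncate at the baseline.
* **Readings.** A patient has an arterial line with probability 0.2,
  emitting 5-minute block medians of the latent series (the archival
  convention for continuously monitored vitals) plus sparse cuff readings;
  other patients get cuff readings on a jittered nursing schedule
  (0.5–1.5 × 20 min) with 3 mmHg measurement noise and no direct MAP.
  These cadences make roughly 48% of all readings invasive, matching the
  reported share in the motivating database.  The jittered (rather than
  Poisson) cuff schedule is deliberate: observation charting is
  scheduled, and cadence alone should not breach the 2-hour gap rule.
* **Corruption.** Each reading is replaced by a plausibility-violating
  artifact with probability 0.02 (the source database's artifact
  prevalence is unpublished; this is a free parameter, not an estimate),
  and monitoring gaps arrive at 0.02/h with uniform 15–150 min durations,
  so a realistic minority of patients fail the frequency rule.
* **Outcomes.** ICU mortality is Bernoulli from the hinge dose-response on
  the **true** latent exposure — change-point 69 mmHg, slope −0.13 per
  mmHg (the headline published estimates), plateau log-odds −5.14 solved
  so the marginal mortality is 3.6%, with modest age and APACHE IVa
  effects (0.015 and 0.03 log-odds per unit).  Because outcomes attach to
  the truth and estimation uses the measured series, measurement-error
  attenuation is itself observable.  AKI and troponin events follow
  analogous hinges with shallower slopes.
* **Reproducibility.** Every patient's stream is keyed by (seed, patient
  id), so cohorts are bit-identical across runs and independent of
  generation order or batch size.

What passing tests on this generator do *not* show: the AR-plus-dips
trajectory has no treatment feedback (vasopressor titration responding to
pressure), no circadian structure, no waveform-level artifacts beyond the
printed filter list, and covariates are mutually independent — so
confounding in the synthetic data is milder than in real EHR data.
Estimator performance here bounds arithmetic and statistical correctness,
not robustness to real-world physiology.

## Numerical choices and degenerate inputs

* Rounding is half-up (`floor(x + 0.5)`), applied once, on the minute grid.
* Profile-likelihood ties break to the smallest candidate; bootstrap
  resampling is seeded explicitly and bit-reproducible.
* Inner logistic fits cap IRLS at 50 iterations and tolerate separation
  warnings (they are suppressed at candidate evaluations, flagged at the
  reported fit).
* Empty inputs: zero readings yield an ineligible patient with
  `max_gap` equal to the window; empty cohorts pass through the exclusion
  cascade; a component with < 120 valued minutes yields a missing
  exposure, excluding the patient from that component's analysis only.
* `standardize()` refuses zero-variance input; `exposure_window()` rejects
  outcome onsets before admission.

## Problem sizes used in validation

The shipped validation uses 20,000-patient cohorts for change-point
recovery (both exposure-level and full-pipeline with artifacts and gaps),
50,000 for the spline linearity check, 1,000 random series for the
exposure-oracle equivalence, and 10 seeded replicates for the recovery
criteria.  At these sizes the exposure-level hinge recovery is exact to
±2 mmHg in roughly 9 of 10 replicates: with the plateau pinned near 0.5%
mortality by the reference-group risk, only a few dozen events occur above
the change-point in 20,000 patients, so the profile's right arm is nearly
flat and the estimate occasionally lands a few mmHg high.  This is a
property of the event regime, not of the implementation (the profile was
cross-checked against an independent refit oracle).

## Known limitations

* The hinge model assumes a single change-point and an exactly flat
  plateau; gradually saturating dose-responses will bias the estimated
  change-point toward the steep region.
* The 5-minute-median archival step is treated as already applied by the
  source system; the package does not undo it, so sub-5-minute excursions
  are invisible by construction.
* SOFA components with missing inputs score 0, which can only
  under-count sepsis.
* The categorical table's overlapping groups are a reporting convention;
  they are not mutually exclusive strata and their ORs are correlated.
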