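# bphinge

Hypotension exposure metrics and hinge (change-point) threshold logistic
regression for septic ICU cohorts.

Intensivists managing sepsis titrate vasopressors against blood-pressure
targets, but the four components — mean (MAP), systolic (SBP), diastolic
(DBP), and pulse pressure (PP = SBP − DBP) — plausibly carry different
risk. `bphinge` is a reusable R implementation of the analysis chain that
question requires, aimed at critical-care epidemiologists working with
minute-level vital-sign EHR data:

* **Preprocessing**: plausibility filters (e.g. SBP ≥ 300 or ≤ 20 mmHg,
  SBP ≤ DBP + 5), invasive-over-cuff source merging, MAP/PP derivation,
  linear interpolation to an integer 1-minute grid, and a 2-hour
  measurement-gap eligibility rule.
* **Exposure metrics**: the lowest pressure sustained cumulatively for
  ≥ 120 minutes (the 120th-smallest minute value), and the time-weighted
  average below a threshold,
  `TWA = Σ max(0, τ − x_t) / LOS` (mmHg).
* **Cohort construction**: SOFA scoring, sepsis (infection + SOFA ≥ 2) and
  septic shock (lactate > 2 mmol/L + vasopressors) definitions, outcome
  windows, norepinephrine-equivalent dose rates, and an auditable
  exclusion cascade.
* **Statistics**: binned moving-average risk curves; penalized thin-plate
  spline logistic regression with GCV (via mgcv); **hinge threshold
  logistic regression** — the core estimator —

  `logit P(y = 1) = α + β_d · max(0, e − x) + γᵀz`,

  where the change-point `e` is found by profile likelihood over a 1-mmHg
  candidate grid and the pre-threshold slope `−β_d` (log-odds per mmHg of
  pressure) measures association strength, with percentile-bootstrap
  intervals; plus categorical odds-ratio tables, subgroup models, and
  generalized VIFs.
* **Synthetic cohort generator**: a septic-ICU simulator with known hinge
  ground truth (change-point 69 mmHg, slope −0.13 per mmHg, ~3.6% ICU
  mortality, ~48% invasive readings) so the whole pipeline is testable
  without restricted patient data.

## Worked example

Simulate 20,000 patients whose true lowest sustained MAP is N(62, 10) mmHg
and whose mortality follows the hinge dose-response, then recover the
change-point:

```r
library(bphinge)

d <- simulate_exposure_cohort(20000, seed = 42)
fit <- fit_hinge_logistic(d, "exposure", "outcome",
                          covariates = c("age", "apache_iva"),
                          nboot = 100, boot_seed = 42)
fit
#> Hinge threshold logistic regression (outcome ~ exposure)
#>   change-point: 68 mmHg (standardized 0.60)
#>   pre-threshold slope: -0.1317 per mmHg (-1.326 per SD)
#>   plateau log-odds (at covariate means): -5.139
#>   95% CI change-point: [63.0, 71.0]; slope: [-0.1456, -0.1212]
```

The generator's truth is a change-point of 69 mmHg with slope −0.13: the
fit lands 1 mmHg and ~0.002 log-odds/mmHg away, with the truth inside both
bootstrap intervals. Predicted mortality along the fitted curve
(covariates at their means) shows the plateau above the change-point:

```r
predict_hinge_curve(fit, c(45, 55, 65, 69, 80))$fit
#> [1] 0.1080 0.0314 0.0086 0.0058 0.0058
```

i.e. ~0.6% mortality anywhere at or above the change-point, rising to 11%
when the lowest sustained MAP is 45 mmHg.

The exposure metrics themselves:

```r
v <- c(rep(55, 90), rep(63, 40), rep(74, 170))   # a minute series, mmHg
lowest_sustained(v, 120)                # 120th smallest minute value
#> [1] 63
time_weighted_average_below(v, 69, 300) # (14*90 + 6*40) / 300
#> [1] 5
```

An end-to-end run — simulate readings, preprocess, build the cohort,
measure exposures, fit all models, render a report:

```r
cfg <- pipeline_config(sim = sim_config(n_patients = 2000, seed = 7),
                       outdir = "run1")
run_pipeline(cfg)
```

or from a shell: `Rscript inst/scripts/bphinge-pipeline.R --n 2000 --seed 7
--outdir run1`. Artifacts are plain CSV/JSON plus a `manifest.json`
recording the configuration hash and seed; reruns are byte-identical.

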