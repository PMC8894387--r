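---
title: "Threshold-effect analysis of a continuous exposure on binary mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-effect analysis of a continuous exposure on binary mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingepoint)
```

## The scientific problem

Many clinical exposures are related to risk non-monotonically: both low and
high values of a biomarker carry excess risk, with a minimum somewhere in
between. A prominent example is the non-HDL-cholesterol to HDL-cholesterol
ratio in septic ICU patients, where 28-day mortality follows a U-shaped
curve. `hingepoint` implements the standard epidemiological workflow for
detecting and quantifying such threshold effects with a binary outcome:

1. descriptive comparison across exposure tertiles (ANOVA / chi-squared),
2. a penalized-spline smooth logistic dose–response curve as a shape
   diagnostic,
3. a **two-piecewise (hinge) logistic model**
   $$\operatorname{logit} p = \beta_0 + \beta_1 x + \beta_2 (x-K)_+ +
   \gamma' z,$$
   whose log-odds is continuous at the turning point $K$, with
   $\mathrm{OR}_{\text{below}} = e^{\beta_1}$ and
   $\mathrm{OR}_{\text{above}} = e^{\beta_1+\beta_2}$,
4. estimation of $K$ by **profile likelihood**: the model is refitted at
   every candidate $K$ on a grid and the likelihood-maximizing candidate is
   kept,
5. a likelihood-ratio test of the one-line (linear) model against the
   two-piecewise model,
6. a nonparametric **bootstrap percentile CI** for $K$,
7. per-SD rescaling of odds ratios ($\mathrm{OR}^{s}$ for exposure SD $s$),
8. **E-value** sensitivity analysis for unmeasured confounding, and
9. missing-indicator handling of incomplete covariates.

Because the motivating data source (a credentialed-access multicentre ICU
database) cannot be redistributed, the package ships a synthetic cohort
generator whose defaults emulate that study population; every stage of the
pipeline is exercised end-to-end on generated data.

## The synthetic cohort and what it does (not) emulate

`cohort_spec()` + `generate_cohort()` draw patient tables with:

- an exposure (`ratio`) from a **lognormal truncated to [0.28, 10]** with
  parameters solved numerically so the truncated mean and SD are 3.43 and
  2.01 — the published cohort reports only these moments and the range, not
  a law, and a truncated lognormal is the natural positive, right-skewed
  choice;
- 28-day death from a Bernoulli draw on the hinge logit with defaults
  $K = 3.3$, $\mathrm{OR}_{\text{below}} = 0.60$,
  $\mathrm{OR}_{\text{above}} = 1.28$ per unit, and an intercept calibrated
  by numerical integration so marginal mortality is 5.94%;
- covariates (age, sex, weight, heart rate, lactate, APACHE IV, SOFA,
  septic shock, infection site) drawn from distributions matched to the
  scale of a real sepsis cohort's baseline table, with **zero effect on the
  logit by default** so the exposure–outcome model is exactly the hinge;
  non-zero effects are opt-in knobs;
- 14-day death as a thinning of 28-day death with conditional probability
  0.7 (the source analysis reports the 14-day outcome only in a supplement
  without counts; 0.7 is our documented choice and guarantees
  `death14 <= death28`);
- covariate missingness injected **completely at random** at configurable
  rates (default: 28.3% lactate, 10.8% APACHE IV, 1.5% weight, 1.0% SOFA,
  0.7% heart rate, mirroring the published missingness footnote). The
  mechanism in the real data is unknown; MCAR is the default and an
  optional MAR tilt (`mar_by`) makes missingness depend on the rank of an
  observed covariate for sensitivity studies. The exposure and the outcome
  are never missing — patients without the lipid panel are an upstream
  exclusion, not an imputation problem.

The generator does **not** emulate: correlations between exposure and
covariates (the joint law is unpublished; the covariate-effect knobs exist
but are zero by default), ICD-coded infection ascertainment, severity-score
computation from raw physiology, or the relational table structure of any
particular ICU database. Passing
tests therefore demonstrate the statistical machinery's correctness and
operating characteristics under the stated generative model — not fidelity
to any individual real cohort.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid for $K$ | 5th–95th exposure percentile, step 0.1 | ratio units | keeps $\ge$ 20 observations per segment at the extremes; the step matches the 1-decimal precision at which turning points are conventionally reported |
| `min_seg` | 20 | patients | a logistic slope estimated from fewer than ~20 observations per segment is unstable |
| LRT df | 1 | — | the hinge coefficient only; the searched $K$ is *not* counted, matching the convention of the software this workflow originates from. This makes the test anti-conservative under a true linear logit; the test suite measures the empirical type-I rate at $\alpha=0.05$ over 200 null simulations rather than pretending the nominal level holds. A Davies-type correction is out of scope. |
| `n_boot` | 500 (min 100) | resamples | percentile CI for $K$; each resample reruns the full grid search (we treat the search, not the fixed-$K$ refit, as the estimator being bootstrapped) |
| missing-indicator threshold | 1% | fraction missing | continuous covariates missing more than 1% get a was-missing indicator; at or below, mean-fill only. The fill constant is the observed mean — the indicator carries the missingness signal regardless of the constant chosen |
| per-SD scale | sample SD of the exposure | ratio units | `OR^sd`; the mean/SD used for standardization are full-cohort sample statistics |
| E-value | rare-outcome form | — | at ~6% outcome prevalence the OR approximates the RR, so $E = \mathrm{RR} + \sqrt{\mathrm{RR}(\mathrm{RR}-1)}$ after inverting protective estimates; the $\sqrt{\mathrm{OR}}$ variant for common outcomes is behind a flag |

## Numerical choices

- **Logistic fitting** is Newton/IRLS on the Bernoulli log-likelihood with
  step-halving (the log-likelihood never decreases), convergence when the
  maximum absolute score drops below `1e-8`, and a hard cap of 100
  iterations. Perfect separation and rank deficiency are *errors naming the
  offending columns*; nothing is penalized silently. Wald (not
  profile-likelihood) intervals are reported, matching the convention of
  standard epidemiological software.
- **Above-segment CI** uses the delta method on $\beta_1+\beta_2$
  ($\mathrm{Var} = V_{11}+V_{22}+2V_{12}$); a reparameterized refit
  (`min(x,K)`, `(x-K)+`) is the cross-check in the test suite.
- **Profile search** warm-starts each candidate fit from its neighbour's
  coefficients (adjacent candidates differ in a single hinge column), and
  ties in the profile are broken toward the smallest $K$ with a warning.
- **Tertiles** use nearest-rank cuts at the order statistics of ranks
  $\lfloor n/3 \rfloor$ and $\lfloor 2n/3 \rfloor$ with ties-to-lower
  labelling: deterministic, permutation-equivariant, and for $n = 724$
  distinct values it yields the conventional 241/241/242 split. A constant
  vector has no tertiles and is an error.
- **Smooth curve**: cubic B-splines (20 basis functions on equally spaced
  knots — equal spacing, the classical P-spline construction, is what makes
  the difference-penalty null space exactly the straight lines in the
  exposure), second-order difference penalty, smoothing parameter by AIC
  over a 30-point log-spaced grid; pointwise (not simultaneous) Wald band
  from the penalized-information covariance; the curve is reported as a
  centered partial effect because the vertical anchoring of such plots is
  conventional. With the penalty sent to infinity the smooth collapses to
  the one-line model (the penalty null space is the linear functions) —
  this, and the exact equality of an unpenalized hinge-basis fit with the
  two-piecewise model, tie the smooth layer to the threshold layer.
- **Proportion CIs** are Wald with $z = 1.959964$ held at full precision
  internally (reported values are rounded to 2 decimals); Wilson is behind
  a flag. No continuity corrections anywhere by default.
- **ANOVA on raw values** is the default group test even for skewed
  variables (matching how published baseline tables are typically
  computed); Kruskal–Wallis is behind a flag.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_patients = 724, seed = 2024)
cohort <- generate_cohort(spec)

result <- threshold_effect(
  add_missing_dummies(cohort),
  outcome = "death28", exposure = "ratio",
  covariates = c("age", "sex", "weight", "heart_rate", "lactate",
                 "lactate_missing", "apache_iv", "apache_iv_missing",
                 "sofa", "septic_shock", "infection_site"),
  n_boot = 500, seed = 2024)
print(result)

evalue_report(result$or_above[["or"]], result$or_above[c("lower", "upper")])
```

Or the whole pipeline from a config:

```{r pipeline, eval = FALSE}
run_pipeline(list(synthetic = list(n_patients = 724), seed = 2024,
                  n_boot = 500, out_dir = "out"))
```

## Design decisions that were genuinely open

- **Bootstrap target**: each resample re-searches $K$ over the full grid
  rather than refitting at the original $\hat K$; re-searching is the
  honest bootstrap of the estimator actually used.
- **Confounder screening** implements only the 10% change-in-estimate rule
  (`|OR_with/OR_without - 1| > 0.10`); outcome-association screening with a
  p-value cutoff is left to the analyst's configuration since no cutoff is
  canonical.
- **Simulation sizes** in the test suite: parameter recovery uses cohorts
  of 20,000 (50 seeds), bootstrap coverage uses 50 replicates of n = 2,000
  with 200 resamples, and the null type-I study uses 200 cohorts of
  n = 724. These sizes give Monte-Carlo noise comfortably smaller than the
  acceptance margins while keeping the suite runnable on a single CPU.
- **Standardized turning point** is computed from the formula
  $(K - \bar x)/s$ with unrounded sample moments; reports that standardize
  with pre-rounded moments can differ in the second decimal.

## Known limitations

- One knot only; no $\ge$ 2-knot segmented models, no smoothly-joined
  spline-hinge hybrids.
- The df=1 LRT's anti-conservativeness under the null is documented and
  measured, not corrected (no Davies-type adjustment).
- No multiple imputation — the missing-indicator method is the point.
- The percentile bootstrap CI for $K$ can be wide and right-skewed at
  moderate n; with very weak threshold signals it may fail to contain the
  point estimate in pathological resampling regimes (a warning is raised).
- E-values are for odds/risk ratios only.
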