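# hingepoint

Threshold-effect ("hinge" or two-piecewise) logistic regression for
continuous exposures and binary outcomes, with the full epidemiological
workflow around it. The motivating use case is U-shaped risk: in septic ICU
patients, 28-day mortality is elevated at both low and high values of the
non-HDL-cholesterol/HDL-cholesterol ratio, with a turning point near 3.3.

## The model

The core inference compares a one-line logistic model with the continuous
two-piecewise model

```
logit p = β₀ + β₁·x + β₂·(x − K)₊ + γ'z
```

where `(x − K)₊ = max(x − K, 0)` is the hinge term and `z` the adjustment
covariates. The per-unit odds ratio is `exp(β₁)` below the turning point
`K` and `exp(β₁ + β₂)` above it (CI by the delta method). `K` itself is
estimated by profile likelihood — the model is refitted at every candidate
on a grid (default 5th–95th percentile, step 0.1) and the
likelihood-maximizing candidate kept — tested against the one-line model by
a df = 1 likelihood-ratio test, and interval-estimated by a nonparametric
bootstrap (percentile CI over re-searched resamples). Odds ratios are also
reported per standard deviation of the exposure (`OR^sd`), and E-values
quantify the unmeasured confounding needed to explain each estimate away.

Supporting layers: tertile descriptive tables (ANOVA / chi-squared / Wald
proportion CIs / unadjusted 2×2 odds ratios), a penalized-spline smooth
logistic dose–response curve with a U-shape diagnostic, missing-indicator
covariate adjustment, and a synthetic sepsis-cohort generator (hinge-logit
risk, calibrated exposure distribution, configurable MCAR/MAR covariate
missingness) so the entire pipeline runs without access to restricted
clinical databases.

## Worked example

```r
library(hingepoint)

cohort <- generate_cohort(cohort_spec(n_patients = 724, seed = 2024))
prepared <- add_missing_dummies(cohort)   # e.g. lactate ~28% missing -> indicator

result <- threshold_effect(
  prepared, outcome = "death28", exposure = "ratio",
  covariates = c("age", "sex", "weight", "heart_rate", "lactate",
                 "apache_iv", "sofa", "septic_shock", "infection_site",
                 attr(prepared, "indicator_columns")),
  n_boot = 500, seed = 2024)
print(result)
```

```
Threshold effect analysis (n = 724 )
                                   Per-unit OR (95% CI)   P        Per-SD OR (95% CI)     P
Model I
  One line effect                  1.05 (0.89, 1.24)      0.530    1.11 (0.80, 1.55)      0.530
Model II
  Turning point (K): 3.0 (standardized -0.25)
  Exposure < K                     0.42 (0.25, 0.72)      0.001    0.17 (0.06, 0.51)      0.001
  Exposure >= K                    1.44 (1.15, 1.80)      0.001    2.11 (1.34, 3.32)      0.001
  P for LRT (one-line vs two-piecewise): 0.000
  95% bootstrap CI for K: 1.4, 6.0 (standardized -1.03, 1.20; B = 500)
```

Read: on this simulated 724-patient cohort (generated with a true turning
point at 3.3 and true per-unit segment ORs 0.60/1.28), the one-line model
sees nothing (OR 1.05, p = 0.53) while the two-piecewise model finds the
U: each unit of the ratio below the estimated turning point of 3.0
multiplies the odds of 28-day death by 0.42, each unit above it by 1.44,
and the LRT rejects the straight-line model. The bootstrap CI for K is
wide — a single cohort of 724 with ~40 deaths carries limited information
about the knot location.

```r
evalue_report(result$or_above[["or"]], result$or_above[c("lower", "upper")],
              label = "above-threshold per-unit OR")
#> E-value [above-threshold per-unit OR]: OR 1.44 (95% CI 1.15, 1.80) -> E = 2.24 point, 1.58 for the CI limit
```

An unmeasured confounder would need odds ratios of ~2.2 with both exposure
and outcome to explain the above-threshold association away.

The full pipeline (descriptive tables, smooth curve, threshold analysis,
E-values, JSON + CSV/Markdown artifacts) runs from one config:

```r
run_pipeline(list(synthetic = list(n_patients = 724), seed = 2024,
                  n_boot = 500, out_dir = "out"))
```

or from the shell:

```sh
Rscript inst/cli/run_analysis.R --config inst/extdata/example_config.yaml
```

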