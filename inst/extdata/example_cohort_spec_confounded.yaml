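# ILLUSTRATIVE cohort spec with NON-ZERO covariate effects on the logit.
# These effect sizes are invented for demonstrating the confounder screen
# and MAR sensitivity hooks; they are not estimates from any real cohort.
n_patients: 2000
turning_point_K: 3.3
slope_below: -0.5108256  # log(0.60)
slope_above: 0.2468601   # log(1.28)
target_prev: 0.0594
seed: 20240
mar_by: sofa
missing_rates:
  lactate: 0.283
  apache_iv: 0.108
covariate_specs:
  age:
    dist: {type: normal, mean: 66.7, sd: 15.0, min: 18, max: 100}
    effect: 0.02          # illustrative: +2% odds per year
  sofa:
    dist: {type: poisson, lambda: 3.1, max: 15}
    effect: 0.15          # illustrative: +16% odds per SOFA point
  septic_shock:
    dist: {type: bernoulli, p: 0.583}
    effect: 0.10          # illustrative
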