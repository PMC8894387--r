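# Demo pipeline configuration: synthetic 724-patient cohort analysed
# end-to-end. Run with
#   Rscript inst/cli/run_analysis.R --config example_config.yaml
synthetic:
  n_patients: 724
outcome: death28
exposure: ratio
n_boot: 500
grid_step: 0.1
seed: 2024
out_dir: out
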